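---
title: "Modeling in vitro gas production kinetics with rumengas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling in vitro gas production kinetics with rumengas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumengas)
```

## The measurement and the models

In the in vitro gas-production technique, a feed sample (here ~500 mg of
silage DM) is incubated at 39 °C in buffered rumen fluid inside a sealed
flask; microbial fermentation releases gas whose cumulative volume,
logged automatically every few minutes, is a proxy for the degradation
kinetics of the substrate. Blank flasks (inoculum and buffer, no
substrate) are incubated in parallel; their mean series is subtracted
from every sample flask to remove gas from microbial activity alone, and
the difference is scaled to mL per 100 mg incubated DM.

Five families are commonly fitted to such curves, and `rumengas`
implements exactly these:

* **Gompertz** `A exp(-B exp(-Ct))` and **Brody** `A(1 - B exp(-Ct))`:
  classical three-parameter curves with a fixed shape, where `A` is
  asymptotic gas production, `C` a fractional rate per hour, and `B` a
  dimensionless shape term connected to the colonization lag.
* **Ørskov & McDonald** `A + B(1 - exp(-Ct))`: `A` is gas from the
  immediately soluble fraction — after blank correction its estimate can
  legitimately be negative — and `B` gas from the insoluble but
  degradable fraction, so total potential gas is `A + B`. Algebraically
  this is a reparameterization of Brody (`A_brody = A + B`,
  `B_brody = B/(A+B)`), and fits of the two families coincide; keeping
  both is conventional because their parameters answer different
  biological questions.
* **Richards** `A(1 - B exp(-Ct))^D`: the extra exponent `D > 0` moves
  the inflection point, letting the sigmoid be asymmetric; `D = 1`
  recovers Brody exactly, so the three-parameter sigmoids are special
  cases.
* **Dual Pool Logistic**
  `A/(1+exp(2-4B(t-C))) + D/(1+exp(2-4E(t-C)))`: two logistic pools —
  fast non-fiber carbohydrates (`A`, rate `B`) and slow fiber (`D`, rate
  `E`) — sharing a common lag `C` in hours.

### The Richards curve below its lag

Published Richards fits for these silages include `B > 1` (e.g. 1.09 at
0 % inclusion). For `B > 1` the base `1 - B exp(-Ct)` is negative until
`t = ln(B)/C`, and a negative number raised to a non-integer power is
undefined. The package defines the curve as zero on that interval
(`base` clamped at 0): biologically, no gas before particle
colonization. The curve stays continuous and non-decreasing across the
clamp boundary, and the analytic Jacobian is zero there (the flat
region carries no information, which is also why all partials vanish).
`B` is stored exactly as estimated; no derived "lag time in hours" is
invented for the three-parameter families, where `B` is dimensionless
despite the field's habit of calling it a colonization time.

## Estimation

All fitting is unweighted nonlinear least squares on whatever curve the
caller supplies — a single flask, replicate flasks stacked as independent
observations, or a pointwise average curve. Two optimizers are
implemented against the shared analytic Jacobians:

* **Modified Gauss–Newton** (default for the 3- and 5-parameter
  families): solves the normal equations and halves the step up to 20
  times until SSE does not increase; cap 100 iterations.
* **Levenberg–Marquardt** (always used for Richards, and as fallback
  when Gauss–Newton fails): damping with Marquardt diagonal scaling,
  λ starting at 1e-3, ×10 on a rejected step, ÷10 on acceptance; cap
  300 iterations.

Both stop when the relative SSE decrease of an accepted step falls below
1e-8 — tight enough that refitting noiseless curves generated from
published parameter sets reproduces them to better than 1e-3 relative
(in practice to machine precision). A fit is reported `converged = FALSE`
when the normal equations are singular, the step search stalls, the
iteration cap is reached, or the Jacobian at the solution is
rank-deficient (an unidentifiable fit, e.g. a curve with one repeated
observation). Non-convergence is a flagged result, never a crash.

Starting values are data-driven: `A0 = 1.05 max(gas)`, `C0 = 0.1/h`,
`B0 = 1` (Brody/Richards) or 2 (Gompertz), `D0 = 1.5`; for
Ørskov & McDonald `A0` is the first observation and `B0` the remaining
span (its `A` is an intercept, not an asymptote); the dual-pool start
splits `1.05 max(gas)` 30/70 between fast and slow pools with
`B0 = 0.2`, `E0 = 0.05`, `C0 = 2` h. These heuristics put every default
start inside the optimizer's basin for curves in the realistic range of
these experiments (asymptotes of 4–7 mL/100 mg DM, rates of
0.05–0.25/h). Exponent arguments are clipped at ±700 before
exponentiation so wandering trial steps return finite limits instead of
overflowing.

Standard errors use the Gauss–Newton curvature approximation
`(J'J)^{-1} SSE/(n - p)` at the optimum. RMSE is reported as
`sqrt(SSE/n)` — the `n` rather than `n - p` denominator is a documented
convention so that reported values are reproducible under one rule.

## Evaluation and model choice

For each converged fit the adequacy report contains:

* **AIC** `n log(SSE/n) + 2(p + 1)`, the Gaussian-likelihood form with
  the residual variance counted as a parameter. Additive constants
  differ across software, so absolute AICs are not comparable to values
  computed elsewhere, but AIC *differences* — and therefore evidence
  ratios `exp(ΔAIC/2)` — are invariant to the constant. This is why the
  package reproduces published evidence ratios (369.5, 6782.2, >10,000)
  from published AICs even though it cannot reproduce the absolute AICs
  without the raw data.
* **R²** of the linear regression of predicted on observed values
  (the squared Pearson correlation of the pairs).
* **Lin's CCC** `2 cov(p,o) / (var(p) + var(o) + (mean(p)-mean(o))²)`
  with population (1/n) moments, per Lin's original definition.
* **MSPE** `mean((o - p)²)` decomposed into mean bias
  `(mean(o)-mean(p))²`, systematic (slope) bias `(s_p - r s_o)²` and
  random error `(1 - r²) s_o²`; the three parts are non-negative and sum
  exactly to the total.

Accuracy is compared pairwise by a two-sided paired t-test on
per-observation squared errors (`d_i = e²_a,i - e²_b,i`). The procedure
behind the published paired-MSPE comparison is not printed anywhere we
could follow, so this simplest defensible paired construction is the
package's documented choice; its type-I error is verified by simulation
to sit at the nominal 5 %. p-values are reported raw — no multiplicity
correction is applied anywhere, matching the source analyses.

## Identity of curves across treatments

Whether two (or more) treatments share one degradation curve is tested
by nested least squares: the *full* model fits each group separately
(equivalently, a dummy-variable parameterization — the test suite
verifies the two give identical SSE), the *reduced* model fits one
parameter set to the pooled observations, and

```
F = [(SSE_r - SSE_f) / (df_r - df_f)] / (SSE_f / df_f),
df_f = N - G·p,  df_r = N - p
```

is referred to `F(df_r - df_f, df_f)`. Pairwise comparisons refit full
and reduced models on each pair's own pooled data rather than taking
contrasts inside one global fit; the two constructions differ
numerically and the pairwise-refit choice is the package's documented
interpretation of the published pairwise table. Replicate flasks enter
as independent observations within their group. Nesting is asserted
(`SSE_r >= SSE_f` up to 1e-8 relative); a violation indicates a fitting
failure and is raised as an error rather than reported as a test result.

## What the simulator does and does not emulate

`generate_experiment()` reproduces the study design: 4 treatments whose
kinetic truths default to the published per-treatment Richards
equations, 6 sample flasks per treatment (24 flasks), 3 blanks, readings
every 5 minutes for 24 h (289 points including t = 0), 500 mg incubated
DM. Defaults are fixed once from the published design and are not tuning
knobs.

The noise model adds Gaussian perturbations to the per-interval gas
increments, truncates each perturbed increment at zero, and
re-accumulates — every simulated raw series is non-decreasing, like a
real cumulative pressure record. The per-increment standard deviation is
`noise_sd/sqrt(n_increments)`, so `noise_sd` (default 0.1 mL/100 mg DM,
inside the published per-fit RMSE range of 0.03–0.19) sets the
cumulative-scale noise magnitude and the truncation almost never binds,
keeping the series unbiased for the truth (verified to |bias| < 0.02 in
the suite). All flasks additionally receive an independent non-negative
background drift (`blank_drift_sd`, default 0.05 mL) representing gas
from the inoculum alone; blanks contain only this drift, which is what
makes mean-blank subtraction a consistent correction.

What it does **not** emulate: pressure-sensor physics and psi→mL
conversion, headspace and temperature effects, venting events,
between-day inoculum variation, or serially correlated sensor error
beyond the accumulated increments. Passing tests on simulated data
therefore demonstrate the correctness and calibration of the *analysis*
under its assumed error model, not robustness to every artifact of real
ANKOM records.

A related deliberate asymmetry: the calibration simulations for the
identity F test and the paired-MSPE test add iid Gaussian noise directly
to the cumulative values, because iid errors are the assumption under
which those tests are exact; the increment-accumulated generator noise
is mildly autocorrelated by construction and is the right model for
end-to-end pipeline tests, not for nominal-size checks.

## Numerical and design choices, in brief

* Convergence tolerance 1e-8 on relative SSE change; step-halving limit
  20; LM damping bounds [1e-12, ∞).
* Problem sizes in the shipped tests and scripts: 289-point 5-minute
  grids for recovery and pipeline checks; 49-point half-hour grids and
  1000 replicates for the F-test size simulation; 1000 and 500
  replicates for paired-MSPE size and power. These sizes give
  Monte-Carlo error comfortably inside the ±2-point assertion bands.
* Significance level 0.05 throughout, configurable in the pipeline; p
  below 1e-4 prints as "<0.0001".
* The "average gas production curve" for model selection is the
  pointwise mean over all sample flasks of all treatments; per-treatment
  curves are pointwise means within treatment. This interpretation (vs
  fitting pooled raw observations) is a documented choice; fitting
  functions accept either form.
* Ørskov & McDonald and Brody fits coincide by reparameterization; both
  are kept, and their near-identical published AICs (1183.57 vs 1183.45,
  the small gap attributable to optimizer stopping points) are
  consistent with that identity.

## Known limitations

* Absolute AICs are comparable only within one run of this package.
* No global optimization: a single data-driven start per fit. Curves far
  outside the realistic gas-production range may need user-supplied
  starts.
* No mixed-effects or heteroscedastic fitting; replicate flasks are
  treated as independent, which understates between-flask correlation if
  flasks share a silo.
* Only full-curve identity is tested, not identity of parameter subsets
  (e.g. equal `A` with free `C`).
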