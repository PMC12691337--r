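Package: rumengas
Title: In Vitro Rumen Gas Production Kinetics: Model Fitting, Evaluation
    and Curve Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits nonlinear kinetic models (Gompertz, Orskov & McDonald,
    Brody, Richards, Dual Pool Logistic) to cumulative in vitro gas
    production curves from rumen-fluid incubations, evaluates model
    adequacy by AIC, R-squared of predicted-on-observed regression, Lin's
    concordance correlation coefficient and mean squared prediction error
    (with bias decomposition), compares model accuracy by paired-MSPE
    tests and AIC evidence ratios, and tests identity of degradation
    curves across treatments with full-versus-reduced extra-sum-of-squares
    F tests. Includes a seeded simulator of ANKOM-style gas-production
    experiments (replicate flasks, blank flasks, 5-minute readings) for
    testing the pipeline against known kinetic truths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
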