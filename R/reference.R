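## Published reference values for BRS Capiacu elephant-grass silage with
## dehydrated cashew pseudo-fruit inclusion. These are inputs to the
## simulator defaults and to evidence-ratio calculations; they are not
## recomputed by this package.

#' Published Richards fits per cashew pseudo-fruit inclusion level
#'
#' Richards parameters (`A`, `B`, `C`, `D`), fit RMSE and R-squared
#' reported for the in vitro gas production of BRS Capiacu elephant-grass
#' silages at 0, 10, 20 and 30 % inclusion of dehydrated cashew
#' pseudo-fruit. These four equations are the default kinetic truths of
#' the experiment simulator ([experiment_config()]).
#'
#' @return data.frame with one row per inclusion level: `inclusion` (%),
#'   `A` (mL/100 mg DM), `B`, `C` (1/h), `D`, `rmse`, `r2`.
#' @export
reference_richards_fits <- function() {
  data.frame(
    inclusion = c(0, 10, 20, 30),
    A = c(4.87, 4.61, 5.66, 6.18),
    B = c(1.09, 1.06, 1.04, 0.97),
    C = c(0.10, 0.12, 0.13, 0.17),
    D = c(2.05, 2.30, 2.50, 1.99),
    rmse = c(0.03, 0.10, 0.19, 0.04),
    r2 = c(0.99, 0.99, 0.99, 0.99)
  )
}

#' Published model-adequacy statistics for the average gas curve
#'
#' Parameter estimates and adequacy criteria (AIC, R-squared of the
#' predicted-on-observed regression, Lin's CCC, MSPE) reported for the
#' five kinetic models fitted to the average cumulative gas curve of the
#' same silage experiment. Useful for evidence-ratio calculations
#' ([evidence_ratio()]) against the published AICs.
#'
#' @return data.frame keyed by `model_id` with columns `A`..`E`, `aic`,
#'   `r2`, `ccc`, `mspe` (`NA` where a model lacks the parameter).
#' @export
reference_model_evaluation <- function() {
  data.frame(
    model_id = c("gompertz", "orskov_mcdonald", "brody", "richards", "dual_pool"),
    A = c(5.03, -0.50, 6.98, 5.36, 1.20),
    B = c(3.89, 7.48, 1.00, 1.03, 0.25),
    C = c(0.19, 0.06, 0.06, 0.13, 3.50),
    D = c(NA, NA, NA, 2.03, 3.76),
    E = c(NA, NA, NA, NA, 0.07),
    aic = c(1130.89, 1183.57, 1183.45, 1119.07, 1136.71),
    r2 = c(0.916, 0.910, 0.910, 0.917, 0.915),
    ccc = c(0.955, 0.953, 0.953, 0.966, 0.965),
    mspe = c(0.247, 0.270, 0.264, 0.246, 0.253)
  )
}
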