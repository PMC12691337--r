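## Model adequacy criteria and multi-model comparison: Gaussian AIC,
## R-squared of the predicted-on-observed regression, Lin's concordance
## correlation coefficient, MSPE with its bias decomposition, AIC
## evidence ratios and the paired-MSPE accuracy test.

#' Gaussian-likelihood AIC for a least-squares fit
#'
#' `AIC = n log(SSE/n) + 2 (p + 1)`, counting the residual variance as an
#' estimated parameter. Only AIC differences (and hence evidence ratios)
#' are comparable across software, since additive constants differ.
#'
#' @param sse residual sum of squares (> 0).
#' @param n_obs number of observations (> `n_params`).
#' @param n_params number of mean-function parameters.
#' @return scalar AIC; `-Inf` with a warning when `sse == 0` (perfect fit).
#' @export
aic_gaussian <- function(sse, n_obs, n_params) {
  stopifnot(n_obs > n_params, sse >= 0)
  if (sse == 0) {
    warning("perfect fit: SSE = 0, AIC is -Inf")
    return(-Inf)
  }
  n_obs * log(sse / n_obs) + 2 * (n_params + 1)
}

#' R-squared of the regression of predicted on observed values
#'
#' The squared Pearson correlation of the (predicted, observed) pairs,
#' i.e. the coefficient of determination of a simple linear regression of
#' predicted data on observed data.
#'
#' @param predicted,observed numeric vectors of equal length >= 3.
#' @return scalar in `[0, 1]`.
#' @export
r2_pred_obs <- function(predicted, observed) {
  check_pairs(predicted, observed)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("R2 undefined for a constant vector")
  stats::cor(predicted, observed)^2
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2 cov(p, o) / (var(p) + var(o) + (mean(p) - mean(o))^2)` with
#' population (1/n) moments. Combines precision (correlation) with
#' accuracy (closeness to the identity line); `CCC = 1` only for exact
#' agreement.
#'
#' @inheritParams r2_pred_obs
#' @return scalar in `[-1, 1]`.
#' @export
ccc <- function(predicted, observed) {
  check_pairs(predicted, observed)
  n <- length(predicted)
  vp <- stats::var(predicted) * (n - 1) / n
  vo <- stats::var(observed) * (n - 1) / n
  if (vp == 0 || vo == 0) stop("CCC undefined for a constant vector")
  cv <- stats::cov(predicted, observed) * (n - 1) / n
  2 * cv / (vp + vo + (mean(predicted) - mean(observed))^2)
}

#' Mean squared prediction error with bias decomposition
#'
#' `MSPE = mean((observed - predicted)^2)`, decomposed into mean bias
#' `(mean(o) - mean(p))^2`, systematic (slope) bias `(s_p - r s_o)^2` and
#' random error `(1 - r^2) s_o^2` (population moments; the three
#' components sum exactly to the total).
#'
#' @inheritParams r2_pred_obs
#' @return list with `mspe`, `mean_bias`, `systematic_bias`,
#'   `random_error`.
#' @export
mspe <- function(predicted, observed) {
  check_pairs(predicted, observed)
  n <- length(predicted)
  so <- sqrt(stats::var(observed) * (n - 1) / n)
  sp <- sqrt(stats::var(predicted) * (n - 1) / n)
  r <- if (so == 0 || sp == 0) 0 else stats::cor(predicted, observed)
  list(
    mspe = mean((observed - predicted)^2),
    mean_bias = (mean(observed) - mean(predicted))^2,
    systematic_bias = (sp - r * so)^2,
    random_error = (1 - r^2) * so^2
  )
}

check_pairs <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("non-finite values in predicted/observed")
  invisible(NULL)
}

#' AIC evidence ratio
#'
#' `exp((AIC_candidate - AIC_best) / 2)`: how many times more likely the
#' lower-AIC model is to minimize information loss than the candidate.
#'
#' @param aic_candidate AIC of the model(s) being compared
#'   (each >= `aic_best`); vectorized.
#' @param aic_best AIC of the best (reference) model.
#' @return numeric >= 1, same length as `aic_candidate`.
#' @examples
#' evidence_ratio(1130.89, 1119.07)
#' @export
evidence_ratio <- function(aic_candidate, aic_best) {
  if (any(aic_candidate < aic_best))
    stop("aic_candidate must be >= aic_best (ratio is against the best model)")
  exp((aic_candidate - aic_best) / 2)
}

#' Paired-MSPE accuracy test between two models
#'
#' Two-sided paired t-test on the per-observation squared prediction
#' errors of two models evaluated on the same observations
#' (`d_i = e_a_i^2 - e_b_i^2`). A small p-value means the two models'
#' accuracies differ.
#'
#' @param errors_a,errors_b per-observation prediction errors
#'   (observed - predicted) of the two models, equal length >= 3.
#' @return p-value in `[0, 1]`; exactly 1 when all `d_i = 0`.
#' @export
paired_mspe_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("error vectors must have equal length")
  if (length(errors_a) < 3) stop("need at least 3 paired errors")
  d <- errors_a^2 - errors_b^2
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0)
    stop("degenerate paired-MSPE case: constant nonzero difference")
  stats::t.test(d)$p.value
}

#' Evaluate one fitted model on a curve
#'
#' One adequacy row: AIC, R-squared of predicted on observed, CCC, MSPE
#' and its decomposition.
#'
#' @param fit a `gas_fit` from [fit_gas_model()].
#' @param curve the [gas_curve()] the fit refers to.
#' @return one-row data.frame.
#' @export
evaluate_fit <- function(fit, curve) {
  stopifnot(inherits(fit, "gas_fit"), inherits(curve, "gas_curve"))
  pred <- model_value(fit$model_id, fit$estimates, curve$times)
  m <- mspe(pred, curve$gas)
  data.frame(
    model_id = fit$model_id,
    converged = fit$converged,
    algorithm = fit$algorithm,
    n_obs = fit$n_obs,
    n_params = length(fit$estimates),
    sse = fit$sse,
    rmse = fit$rmse,
    aic = aic_gaussian(fit$sse, fit$n_obs, length(fit$estimates)),
    r2 = r2_pred_obs(pred, curve$gas),
    ccc = ccc(pred, curve$gas),
    mspe = m$mspe,
    mspe_mean_bias = m$mean_bias,
    mspe_systematic_bias = m$systematic_bias,
    mspe_random_error = m$random_error
  )
}

#' Rank candidate models fitted to the same curve
#'
#' Builds the model-adequacy table (parameters with standard errors, AIC,
#' R-squared, CCC, MSPE per model), selects the lowest-AIC converged
#' model, and computes AIC evidence ratios against it together with the
#' pairwise paired-MSPE p-value matrix.
#'
#' @param fits list of `gas_fit` objects (>= 2) on the same curve.
#' @param curve the shared [gas_curve()].
#' @return object of class `gas_model_ranking`: `report` (data.frame with
#'   an `evidence_ratio` column), `best_model`, `pmspe_pvalues`
#'   (symmetric matrix, unit diagonal) and `estimates` (per-model
#'   parameter/SE table).
#' @export
rank_models <- function(fits, curve) {
  if (length(fits) < 2) stop("need at least 2 fits to compare models")
  stopifnot(all(vapply(fits, inherits, logical(1), "gas_fit")))
  ids <- make.unique(vapply(fits, `[[`, character(1), "model_id"))
  report <- do.call(rbind, lapply(fits, evaluate_fit, curve = curve))
  ok <- report$converged
  if (!any(ok)) stop("no converged fit to rank")
  if (!all(ok))
    message("excluding non-converged fit(s) from best-model selection: ",
            paste(report$model_id[!ok], collapse = ", "))
  best_aic <- min(report$aic[ok])
  best_model <- report$model_id[ok][which.min(report$aic[ok])]
  report$evidence_ratio <- ifelse(
    ok & report$aic >= best_aic, exp((report$aic - best_aic) / 2), NA_real_)
  preds <- lapply(fits, function(f)
    model_value(f$model_id, f$estimates, curve$times))
  k <- length(fits)
  pm <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(pm) <- 1
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    p <- paired_mspe_test(curve$gas - preds[[i]], curve$gas - preds[[j]])
    pm[i, j] <- pm[j, i] <- p
  }
  all_pars <- c("A", "B", "C", "D", "E")
  est <- do.call(rbind, lapply(fits, function(f) {
    d <- data.frame(model_id = f$model_id)
    for (nm in all_pars) {
      d[[nm]] <- if (nm %in% names(f$estimates))
        unname(f$estimates[[nm]]) else NA_real_
      d[[paste0("se_", nm)]] <- if (nm %in% names(f$std_errors))
        unname(f$std_errors[[nm]]) else NA_real_
    }
    d
  }))
  structure(
    list(report = report, best_model = best_model,
         pmspe_pvalues = pm, estimates = est),
    class = "gas_model_ranking"
  )
}

#' @export
print.gas_model_ranking <- function(x, ...) {
  cat("<gas_model_ranking> best model by AIC:", x$best_model, "\n\n")
  cols <- c("model_id", "aic", "r2", "ccc", "mspe", "evidence_ratio")
  print(x$report[, cols], row.names = FALSE, digits = 4)
  cat("\npairwise paired-MSPE p-values:\n")
  print(round(x$pmspe_pvalues, 4))
  invisible(x)
}
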