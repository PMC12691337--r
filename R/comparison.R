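## Identity of degradation curves across treatments: extra-sum-of-squares
## F test between a "full" model (separate parameters per treatment,
## equivalent to a dummy-variable parameterization) and a "reduced" model
## (one global parameter set pooled over treatments).

#' Stack several curves into one set of observations
#'
#' Pools the observations of multiple [gas_curve()] objects (e.g.
#' replicate flasks of one treatment) into a single curve; tied times are
#' kept as independent observations.
#'
#' @param curves list of [gas_curve()] objects.
#' @return a pooled [gas_curve()].
#' @export
pool_curves <- function(curves) {
  gas_curve(
    times = unlist(lapply(curves, `[[`, "times"), use.names = FALSE),
    gas = unlist(lapply(curves, `[[`, "gas"), use.names = FALSE),
    treatment_id = "pooled"
  )
}

#' Full model: independent fits per treatment group
#'
#' Fits the model separately to each group's curve; `sse_full` is the sum
#' of the group SSEs and `df_full = N - G * p` (total observations minus
#' one parameter set per group). Identical to the dummy-variable
#' parameterization with a full set of interaction dummies.
#'
#' @param group_curves named list of [gas_curve()] objects, one per
#'   treatment group (replicate observations already stacked within each).
#' @param model model family or id.
#' @param ... passed to [fit_gas_model()].
#' @return list with `fits` (per group), `sse_full`, `df_full`.
#' @export
fit_full <- function(group_curves, model, ...) {
  if (length(group_curves) < 2) stop("need at least 2 treatment groups")
  model <- as_gas_model(model)
  nm <- names(group_curves)
  if (is.null(nm)) nm <- paste0("group", seq_along(group_curves))
  fits <- lapply(group_curves, fit_gas_model, model = model, ...)
  bad <- !vapply(fits, `[[`, logical(1), "converged")
  if (any(bad))
    stop("full-model fit did not converge for group(s): ",
         paste(nm[bad], collapse = ", "))
  n_tot <- sum(vapply(group_curves, function(cv) length(cv$times), integer(1)))
  list(fits = stats::setNames(fits, nm),
       sse_full = sum(vapply(fits, `[[`, numeric(1), "sse")),
       df_full = n_tot - length(fits) * model$n_params)
}

#' Reduced model: one global fit pooled over treatments
#'
#' @inheritParams fit_full
#' @return list with `fit`, `sse_reduced`, `df_reduced = N - p`.
#' @export
fit_reduced <- function(group_curves, model, ...) {
  if (length(group_curves) < 1) stop("no curves to pool")
  model <- as_gas_model(model)
  pooled <- pool_curves(group_curves)
  fit <- fit_gas_model(pooled, model, ...)
  if (!fit$converged) stop("reduced (pooled) model fit did not converge")
  list(fit = fit,
       sse_reduced = fit$sse,
       df_reduced = length(pooled$times) - model$n_params)
}

#' Extra-sum-of-squares F test between nested curve fits
#'
#' `F = [(SSE_r - SSE_f)/(df_r - df_f)] / (SSE_f/df_f)` referred to the
#' F distribution with `(df_r - df_f, df_f)` degrees of freedom. Rejecting
#' means a single global curve is not adequate for the groups compared.
#'
#' @param sse_full,df_full SSE and residual df of the full model.
#' @param sse_reduced,df_reduced SSE and residual df of the reduced model.
#' @param pair optional label (e.g. `c("0", "30")`) carried in the result.
#' @return object of class `identity_test`: the inputs plus
#'   `f_statistic` and `p_value`.
#' @export
identity_f_test <- function(sse_full, df_full, sse_reduced, df_reduced,
                            pair = NULL) {
  stopifnot(df_reduced > df_full, df_full > 0)
  if (sse_reduced < sse_full * (1 - 1e-8))
    stop("sse_reduced < sse_full: nesting violated, fitting failure likely")
  f <- max(0, (sse_reduced - sse_full) / (df_reduced - df_full) /
                (sse_full / df_full))
  structure(
    list(pair = pair,
         sse_full = sse_full, df_full = df_full,
         sse_reduced = sse_reduced, df_reduced = df_reduced,
         f_statistic = f,
         p_value = stats::pf(f, df_reduced - df_full, df_full,
                             lower.tail = FALSE)),
    class = "identity_test"
  )
}

#' @export
print.identity_test <- function(x, ...) {
  lab <- if (is.null(x$pair)) "all groups" else paste(x$pair, collapse = " vs ")
  cat(sprintf("<identity_test> %s: F(%d, %d) = %.4g, p %s\n",
              lab, x$df_reduced - x$df_full, x$df_full, x$f_statistic,
              format_pvalue(x$p_value)))
  invisible(x)
}

#' Identity test for a set of treatment curves
#'
#' Convenience wrapper: full fits per group, reduced fit on the pool,
#' then the extra-sum-of-squares F test.
#'
#' @inheritParams fit_full
#' @return an `identity_test` (with the component fits attached as
#'   attributes `full` and `reduced`).
#' @export
identity_test <- function(group_curves, model, ...) {
  full <- fit_full(group_curves, model, ...)
  red <- fit_reduced(group_curves, model, ...)
  out <- identity_f_test(full$sse_full, full$df_full,
                         red$sse_reduced, red$df_reduced,
                         pair = names(group_curves))
  attr(out, "full") <- full
  attr(out, "reduced") <- red
  out
}

#' Pairwise identity tests across all treatment pairs
#'
#' Runs [identity_test()] for every unordered pair of groups (each pair
#' refit on its own pooled data) and returns the upper-triangular p-value
#' matrix. Failing pairs are reported as `NA` with a warning and the
#' remaining pairs are still computed.
#'
#' @inheritParams fit_full
#' @return object of class `pairwise_identity`: `p_values` (matrix with
#'   `NA` lower triangle and diagonal) and `tests` (list of
#'   `identity_test` objects keyed `"a|b"`).
#' @export
pairwise_identity <- function(group_curves, model, ...) {
  if (length(group_curves) < 2) stop("need at least 2 treatment groups")
  nm <- names(group_curves)
  if (is.null(nm)) nm <- paste0("group", seq_along(group_curves))
  k <- length(group_curves)
  pv <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  tests <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    res <- tryCatch(
      identity_test(group_curves[c(i, j)], model, ...),
      error = function(e) {
        warning("identity test failed for pair ", nm[i], " vs ", nm[j],
                ": ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) {
      pv[i, j] <- res$p_value
      tests[[paste(nm[i], nm[j], sep = "|")]] <- res
    }
  }
  structure(list(p_values = pv, tests = tests), class = "pairwise_identity")
}

#' @export
print.pairwise_identity <- function(x, ...) {
  cat("<pairwise_identity> full-vs-reduced p-values (upper triangle):\n")
  disp <- x$p_values
  disp[] <- ifelse(is.na(disp), "-", format_pvalue(disp))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Display convention for small p-values
#'
#' @param p numeric p-value(s).
#' @param floor values below this print as `"<floor"` (default 1e-4,
#'   i.e. `"<0.0001"`).
#' @return character vector.
#' @export
format_pvalue <- function(p, floor = 1e-4) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
                sprintf("%.4f", p)))
}
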