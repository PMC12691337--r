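## Nonlinear least-squares fitting of gas-production curves.
##
## Two optimizers are provided: a modified Gauss-Newton with step-halving
## (default for the three- and five-parameter models, 100 iterations) and
## Levenberg-Marquardt with adaptive damping (used for Richards, which is
## prone to Gauss-Newton divergence, and as fallback; 300 iterations).
## Both minimize unweighted SSE and stop when the relative SSE decrease
## of an accepted step falls below `tol`.

#' A single cumulative gas-production curve
#'
#' Container for one blank-corrected cumulative gas series (one flask, a
#' pooled treatment group, or an average curve). Observations are sorted
#' by time; tied times are allowed (replicate flasks stacked as
#' independent observations).
#'
#' @param times incubation times, hours, non-negative.
#' @param gas blank-corrected cumulative gas, mL per 100 mg incubated DM.
#'   Small negatives (blank-correction noise) are tolerated; a warning is
#'   issued when `min(gas) < -0.5`.
#' @param treatment_id,replicate_id optional labels.
#' @return object of class `gas_curve`.
#' @export
gas_curve <- function(times, gas, treatment_id = NA_character_,
                      replicate_id = NA_character_) {
  if (length(times) != length(gas)) stop("times and gas must have equal length")
  if (!all(is.finite(times)) || !all(is.finite(gas)))
    stop("times and gas must be finite")
  if (any(times < 0)) stop("times must be >= 0")
  o <- order(times)
  if (min(gas) < -0.5)
    warning("gas has values below -0.5 mL/100 mg DM; check blank correction")
  structure(
    list(times = times[o], gas = gas[o],
         treatment_id = treatment_id, replicate_id = replicate_id),
    class = "gas_curve"
  )
}

#' @export
print.gas_curve <- function(x, ...) {
  cat("<gas_curve>", length(x$times), "obs,",
      sprintf("t in [%g, %g] h, gas in [%.3g, %.3g] mL/100 mg DM\n",
              min(x$times), max(x$times), min(x$gas), max(x$gas)))
  if (!is.na(x$treatment_id)) cat("  treatment:", x$treatment_id, "\n")
  invisible(x)
}

#' Data-driven starting values for a model fit
#'
#' Heuristics: `A0 = 1.05 max(gas)` with `C0 = 0.1/h` for the
#' asymptote-`A` models (`B0 = 1` for Brody/Richards, 2 for Gompertz,
#' `D0 = 1.5` for Richards); for Orskov & McDonald, `A0` is the first
#' observation and `B0` the remaining span; the dual-pool start splits
#' `1.05 max(gas)` 30/70 between the fast and slow pools with rates
#' `B0 = 0.2`, `E0 = 0.05` and lag `C0 = 2` h.
#'
#' @param curve a [gas_curve()].
#' @param model a [gas_model()] or id string.
#' @return named numeric start vector, valid for the model.
#' @export
default_start <- function(curve, model) {
  model <- as_gas_model(model)
  stopifnot(inherits(curve, "gas_curve"))
  top <- max(curve$gas)
  if (top <= 0) stop("degenerate curve: no positive gas values, nothing to fit")
  A0 <- 1.05 * top
  switch(model$model_id,
    gompertz = c(A = A0, B = 2, C = 0.1),
    brody = c(A = A0, B = 1, C = 0.1),
    richards = c(A = A0, B = 1, C = 0.1, D = 1.5),
    orskov_mcdonald = c(A = curve$gas[1], B = A0 - curve$gas[1], C = 0.1),
    dual_pool = c(A = 0.3 * A0, B = 0.2, C = 2, D = 0.7 * A0, E = 0.05)
  )
}

sse_of <- function(model_id, p, curve) {
  r <- curve$gas - model_value(model_id, p, curve$times)
  if (any(!is.finite(r))) return(Inf)
  sum(r^2)
}

new_fit <- function(model, p, curve, sse, n_iter, converged, algorithm, trace) {
  n <- length(curve$times)
  k <- model$n_params
  se <- rep(NA_real_, k)
  if (converged && n > k && sse >= 0) {
    J <- model_jacobian(model$model_id, p, curve$times)
    if (any(!is.finite(J)) || qr(J)$rank < k) {
      converged <- FALSE        # unidentifiable at the solution
    } else {
      JtJ <- crossprod(J)
      cov_u <- tryCatch(solve(JtJ), error = function(e) NULL)
      if (!is.null(cov_u)) {
        s2 <- sse / (n - k)
        d <- diag(cov_u) * s2
        se <- ifelse(d >= 0, sqrt(d), NA_real_)
      }
    }
  }
  names(se) <- model$param_names
  structure(
    list(model_id = model$model_id,
         estimates = p,
         std_errors = se,
         sse = sse,
         rmse = sqrt(sse / n),   # n-denominator convention, documented
         n_obs = n,
         n_iter = n_iter,
         converged = converged,
         algorithm = algorithm,
         sse_trace = trace),
    class = "gas_fit"
  )
}

#' @export
print.gas_fit <- function(x, ...) {
  cat("<gas_fit>", x$model_id, "via", x$algorithm,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  est <- sprintf("%.4g", x$estimates)
  se <- ifelse(is.na(x$std_errors), "NA", sprintf("%.3g", x$std_errors))
  cat(paste0("  ", names(x$estimates), " = ", est, " ± ", se,
             collapse = "\n"), "\n")
  cat(sprintf("  SSE %.6g  RMSE %.4g  n %d  iterations %d\n",
              x$sse, x$rmse, x$n_obs, x$n_iter))
  invisible(x)
}

#' Modified Gauss-Newton fit with step-halving
#'
#' Iterates the Gauss-Newton normal equations with up to 20 step
#' halvings per iteration until the relative SSE decrease of an accepted
#' step is below `tol`. Singular normal equations or exhausted halvings
#' end the fit with `converged = FALSE` rather than an error.
#'
#' @param curve a [gas_curve()].
#' @param model model family or id.
#' @param start starting parameter vector; defaults to [default_start()].
#' @param max_iter iteration cap (default 100).
#' @param tol relative SSE convergence tolerance.
#' @return a `gas_fit` object (see [fit_gas_model()]).
#' @export
fit_gauss_newton <- function(curve, model, start = NULL, max_iter = 100,
                             tol = 1e-8) {
  fit_engine(curve, model, start, max_iter, tol, algorithm = "gauss_newton")
}

#' Levenberg-Marquardt fit
#'
#' Damped least squares with Marquardt diagonal scaling: the damping
#' parameter starts at 1e-3, is multiplied by 10 on a rejected step and
#' divided by 10 on an accepted one. More robust than Gauss-Newton for
#' the highly nonlinear Richards family.
#'
#' @inheritParams fit_gauss_newton
#' @param max_iter iteration cap (default 300).
#' @return a `gas_fit` object.
#' @export
fit_lm <- function(curve, model, start = NULL, max_iter = 300, tol = 1e-8) {
  fit_engine(curve, model, start, max_iter, tol, algorithm = "levenberg_marquardt")
}

fit_engine <- function(curve, model, start, max_iter, tol, algorithm) {
  model <- as_gas_model(model)
  stopifnot(inherits(curve, "gas_curve"), max_iter >= 1)
  if (length(curve$times) < model$n_params + 1)
    stop("curve has fewer observations than parameters + 1")
  p <- if (is.null(start)) default_start(curve, model)
       else as.numeric_params(start, model)
  t <- curve$times
  y <- curve$gas
  lambda <- 1e-3
  sse <- sse_of(model$model_id, p, curve)
  if (!is.finite(sse)) stop("starting values give non-finite predictions")
  trace <- sse
  converged <- sse == 0
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    r <- y - model_value(model$model_id, p, t)
    J <- model_jacobian(model$model_id, p, t)
    if (any(!is.finite(J))) break
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    accepted <- FALSE
    if (algorithm == "gauss_newton") {
      delta <- tryCatch(solve(JtJ, g), error = function(e) NULL)
      if (is.null(delta) || any(!is.finite(delta))) break   # singular
      step <- 1
      for (h in seq_len(21)) {            # full step + 20 halvings
        p_new <- p + step * as.numeric(delta)
        names(p_new) <- names(p)
        sse_new <- sse_of(model$model_id, p_new, curve)
        if (sse_new <= sse) { accepted <- TRUE; break }
        step <- step / 2
      }
    } else {
      dscale <- pmax(diag(JtJ), 1e-12)
      for (h in seq_len(30)) {            # raise damping until a step helps
        delta <- tryCatch(solve(JtJ + lambda * diag(dscale, nrow(JtJ)), g),
                          error = function(e) NULL)
        if (is.null(delta) || any(!is.finite(delta))) { lambda <- lambda * 10; next }
        p_new <- p + as.numeric(delta)
        names(p_new) <- names(p)
        sse_new <- sse_of(model$model_id, p_new, curve)
        if (sse_new <= sse) {
          accepted <- TRUE
          lambda <- max(lambda / 10, 1e-12)
          break
        }
        lambda <- lambda * 10
      }
    }
    if (!accepted) break
    rel <- (sse - sse_new) / max(sse, .Machine$double.xmin)
    p <- p_new
    sse <- sse_new
    trace <- c(trace, sse)
    if (rel < tol || sse == 0) converged <- TRUE
  }
  new_fit(model, p, curve, sse, iter, converged, algorithm, trace)
}

#' Fit a kinetic model to a gas curve
#'
#' Dispatching front end: the Richards model always uses
#' Levenberg-Marquardt; other models are fitted by modified Gauss-Newton
#' first and fall back to Levenberg-Marquardt if Gauss-Newton fails to
#' converge. Standard errors come from the Gauss-Newton approximation
#' `(J'J)^-1 * SSE/(n - p)` at the optimum.
#'
#' @inheritParams fit_gauss_newton
#' @param max_iter_gn,max_iter_lm iteration caps for the two algorithms.
#' @return object of class `gas_fit`: `estimates`, `std_errors`, `sse`,
#'   `rmse` (`sqrt(sse/n)`), `n_obs`, `n_iter`, `converged`, `algorithm`
#'   and the accepted-step `sse_trace`.
#' @examples
#' truth <- c(A = 6.18, B = 0.97, C = 0.17, D = 1.99)
#' tt <- seq(0, 24, by = 1)
#' cv <- gas_curve(tt, gas_evaluate("richards", truth, tt))
#' fit_gas_model(cv, "richards")
#' @export
fit_gas_model <- function(curve, model, start = NULL, tol = 1e-8,
                          max_iter_gn = 100, max_iter_lm = 300) {
  model <- as_gas_model(model)
  if (model$model_id == "richards")
    return(fit_lm(curve, model, start, max_iter_lm, tol))
  fit <- fit_gauss_newton(curve, model, start, max_iter_gn, tol)
  if (!fit$converged) {
    fallback <- fit_lm(curve, model, start, max_iter_lm, tol)
    if (fallback$converged || fallback$sse < fit$sse) return(fallback)
  }
  fit
}
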