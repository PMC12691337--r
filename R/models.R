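#' @keywords internal
"_PACKAGE"

## Model families -----------------------------------------------------------

MODEL_IDS <- c("gompertz", "orskov_mcdonald", "brody", "richards", "dual_pool")

MODEL_PARAMS <- list(
  gompertz        = c("A", "B", "C"),
  orskov_mcdonald = c("A", "B", "C"),
  brody           = c("A", "B", "C"),
  richards        = c("A", "B", "C", "D"),
  dual_pool       = c("A", "B", "C", "D", "E")
)

#' Kinetic model families for cumulative gas production
#'
#' Constructs one of the five gas-production model families. All models describe cumulative gas `P(t)` (mL per 100 mg of
#' incubated DM) as a function of incubation time `t` (hours):
#'
#' \describe{
#'   \item{gompertz}{`P(t) = A exp(-B exp(-C t))` — `A` asymptotic gas,
#'     `B` shape/lag-related term, `C` fractional rate (1/h).}
#'   \item{orskov_mcdonald}{`P(t) = A + B (1 - exp(-C t))` — `A` gas from
#'     the soluble fraction (may be negative after blank correction), `B`
#'     gas from the insoluble-but-degradable fraction, `C` its rate.}
#'   \item{brody}{`P(t) = A (1 - B exp(-C t))` — monomolecular.}
#'   \item{richards}{`P(t) = A (1 - B exp(-C t))^D` — the extra shape
#'     parameter `D` frees the inflection point; `D = 1` recovers Brody.
#'     For `B > 1` the base is negative below the lag time; the curve is
#'     clamped at zero there (no gas before colonization).}
#'   \item{dual_pool}{`P(t) = A/(1 + exp(2 - 4B(t - C))) +
#'     D/(1 + exp(2 - 4E(t - C)))` — two logistic pools: fast
#'     non-fiber carbohydrates (volume `A`, rate `B`) and slow fiber
#'     (volume `D`, rate `E`) sharing lag `C` (hours).}
#' }
#'
#' @param model_id one of `"gompertz"`, `"orskov_mcdonald"`, `"brody"`,
#'   `"richards"`, `"dual_pool"` (alias `"dual_pool_logistic"` accepted).
#' @return an object of class `gas_model` with fields `model_id`,
#'   `param_names` and `n_params`.
#' @examples
#' gas_model("richards")
#' @export
gas_model <- function(model_id) {
  if (identical(model_id, "dual_pool_logistic")) model_id <- "dual_pool"
  model_id <- match.arg(model_id, MODEL_IDS)
  structure(
    list(model_id = model_id,
         param_names = MODEL_PARAMS[[model_id]],
         n_params = length(MODEL_PARAMS[[model_id]])),
    class = "gas_model"
  )
}

as_gas_model <- function(model) {
  if (inherits(model, "gas_model")) model else gas_model(model)
}

#' @export
print.gas_model <- function(x, ...) {
  cat("<gas_model>", x$model_id, "—", x$n_params, "parameters:",
      paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Validate a parameter vector against a model's constraints
#'
#' Checks length, names and sign constraints: `C > 0` for every model,
#' `D > 0` for Richards, `E > 0` for the dual-pool model, and `A > 0` for
#' every model except Orskov & McDonald (whose soluble-fraction intercept
#' can be negative after blank correction).
#'
#' @param model a [gas_model()] or model id string.
#' @param params named (or positional) numeric vector of parameters.
#' @return the parameter vector, named in canonical order (invisibly on
#'   success); signals an error on violation.
#' @export
validate_params <- function(model, params) {
  model <- as_gas_model(model)
  params <- as.numeric_params(params, model)
  if (any(!is.finite(params)))
    stop("non-finite parameter for model '", model$model_id, "'")
  if (params[["C"]] <= 0)
    stop("rate parameter C must be > 0 (model '", model$model_id, "')")
  if (model$model_id == "richards" && params[["D"]] <= 0)
    stop("Richards shape parameter D must be > 0")
  if (model$model_id == "dual_pool" && params[["E"]] <= 0)
    stop("dual-pool fiber rate E must be > 0")
  if (model$model_id != "orskov_mcdonald" && params[["A"]] <= 0)
    stop("asymptote/pool parameter A must be > 0 (model '",
         model$model_id, "')")
  invisible(params)
}

as.numeric_params <- function(params, model) {
  p <- unlist(params, use.names = TRUE)
  if (length(p) != model$n_params)
    stop("expected ", model$n_params, " parameters for '", model$model_id,
         "', got ", length(p))
  if (!is.null(names(p)) && all(nzchar(names(p)))) {
    if (!setequal(names(p), model$param_names))
      stop("parameter names must be ", paste(model$param_names, collapse = ","))
    p <- p[model$param_names]
  } else {
    names(p) <- model$param_names
  }
  p
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) == 0 || any(!is.finite(times)))
    stop("times must be finite numeric")
  if (any(times < 0)) stop("times must be >= 0 hours")
  invisible(times)
}

# exp() with the argument clipped at +/-700 so LM trial steps cannot
# overflow to Inf; the clipped value is the exact limit for all practical
# purposes at double precision.
safe_exp <- function(x) exp(pmin(pmax(x, -700), 700))

## Closed forms, no validation: the optimizers call these on trial points.
model_value <- function(model_id, p, t) {
  switch(model_id,
    gompertz = p[["A"]] * safe_exp(-p[["B"]] * safe_exp(-p[["C"]] * t)),
    orskov_mcdonald = p[["A"]] + p[["B"]] * (1 - safe_exp(-p[["C"]] * t)),
    brody = p[["A"]] * (1 - p[["B"]] * safe_exp(-p[["C"]] * t)),
    richards = {
      u <- pmax(0, 1 - p[["B"]] * safe_exp(-p[["C"]] * t))
      p[["A"]] * u^p[["D"]]
    },
    dual_pool = {
      s1 <- 1 / (1 + safe_exp(2 - 4 * p[["B"]] * (t - p[["C"]])))
      s2 <- 1 / (1 + safe_exp(2 - 4 * p[["E"]] * (t - p[["C"]])))
      p[["A"]] * s1 + p[["D"]] * s2
    },
    stop("unknown model id: ", model_id)
  )
}

model_jacobian <- function(model_id, p, t) {
  J <- switch(model_id,
    gompertz = {
      e <- safe_exp(-p[["C"]] * t)
      f <- safe_exp(-p[["B"]] * e)
      cbind(A = f,
            B = -p[["A"]] * e * f,
            C = p[["A"]] * p[["B"]] * t * e * f)
    },
    orskov_mcdonald = {
      e <- safe_exp(-p[["C"]] * t)
      cbind(A = rep(1, length(t)),
            B = 1 - e,
            C = p[["B"]] * t * e)
    },
    brody = {
      e <- safe_exp(-p[["C"]] * t)
      cbind(A = 1 - p[["B"]] * e,
            B = -p[["A"]] * e,
            C = p[["A"]] * p[["B"]] * t * e)
    },
    richards = {
      e <- safe_exp(-p[["C"]] * t)
      u <- 1 - p[["B"]] * e
      live <- u > 0                       # below the lag the curve is flat 0
      u <- pmax(u, 0)
      uD <- u^p[["D"]]
      uD1 <- ifelse(live, u^(p[["D"]] - 1), 0)
      cbind(A = uD,
            B = -p[["A"]] * p[["D"]] * uD1 * e,
            C = p[["A"]] * p[["D"]] * uD1 * p[["B"]] * t * e,
            D = ifelse(live, p[["A"]] * uD * log(u), 0))
    },
    dual_pool = {
      x1 <- 2 - 4 * p[["B"]] * (t - p[["C"]])
      x2 <- 2 - 4 * p[["E"]] * (t - p[["C"]])
      e1 <- safe_exp(x1); e2 <- safe_exp(x2)
      d1 <- e1 / (1 + e1)^2; d2 <- e2 / (1 + e2)^2
      cbind(A = 1 / (1 + e1),
            B = p[["A"]] * 4 * (t - p[["C"]]) * d1,
            C = -(p[["A"]] * 4 * p[["B"]] * d1 + p[["D"]] * 4 * p[["E"]] * d2),
            D = 1 / (1 + e2),
            E = p[["D"]] * 4 * (t - p[["C"]]) * d2)
    },
    stop("unknown model id: ", model_id)
  )
  J
}

#' Evaluate a gas-production model on a time grid
#'
#' @param model a [gas_model()] or model id string.
#' @param params named numeric parameter vector (validated; see
#'   [validate_params()]).
#' @param times non-negative incubation times in hours, strictly increasing.
#' @return numeric vector of predicted cumulative gas (mL/100 mg DM), one
#'   value per time point.
#' @examples
#' p <- c(A = 6.18, B = 0.97, C = 0.17, D = 1.99)
#' gas_evaluate("richards", p, c(0, 6, 12, 24))
#' @export
gas_evaluate <- function(model, params, times) {
  model <- as_gas_model(model)
  params <- validate_params(model, params)
  check_times(times)
  model_value(model$model_id, params, times)
}

#' Analytic Jacobian of a gas-production model
#'
#' Partial derivatives of the predicted curve with respect to each
#' parameter, one row per time point, columns in canonical parameter
#' order. These are the exact derivatives of the closed forms (for the
#' clamped Richards region below the lag, all partials are zero).
#'
#' @inheritParams gas_evaluate
#' @return numeric matrix, `length(times)` by `n_params`.
#' @export
gas_jacobian <- function(model, params, times) {
  model <- as_gas_model(model)
  params <- validate_params(model, params)
  check_times(times)
  model_jacobian(model$model_id, params, times)
}

#' Total potential gas production implied by a fitted model
#'
#' The long-incubation-time plateau: `A` for Gompertz, Brody and Richards;
#' `A + B` for Orskov & McDonald (soluble plus degradable fractions);
#' `A + D` for the dual-pool model (non-fiber plus fiber pools).
#'
#' @inheritParams gas_evaluate
#' @return scalar, mL gas per 100 mg DM.
#' @export
gas_asymptote <- function(model, params) {
  model <- as_gas_model(model)
  params <- validate_params(model, params)
  switch(model$model_id,
    gompertz = ,
    brody = ,
    richards = unname(params[["A"]]),
    orskov_mcdonald = unname(params[["A"]] + params[["B"]]),
    dual_pool = unname(params[["A"]] + params[["D"]])
  )
}
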