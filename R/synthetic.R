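## Seeded simulator of an ANKOM-style in vitro gas-production experiment:
## four silage treatments with known Richards kinetics, replicate sample
## flasks, blank flasks, cumulative readings every 5 minutes over 24 h.
##
## Noise model: Gaussian perturbations on the per-interval gas increments,
## truncated at zero and re-accumulated, so every simulated raw series is
## non-decreasing like a real cumulative pressure record. Per-increment
## sd is noise_sd/sqrt(n_increments): the cumulative-scale noise magnitude
## is then ~noise_sd and the truncation almost never binds, keeping the
## series unbiased for the kinetic truth.

#' Default experiment configuration
#'
#' The default emulates the source study's design: 4 treatments (0, 10,
#' 20, 30 % dehydrated cashew pseudo-fruit inclusion) whose kinetic
#' truths are the published per-treatment Richards equations
#' ([reference_richards_fits()]), 6 sample flasks per treatment (24
#' total), 3 blank flasks, readings every 5 minutes for 24 h, 500 mg
#' incubated DM per flask, and noise sd 0.1 mL/100 mg DM (within the
#' published per-fit RMSE range of 0.03-0.19).
#'
#' @param treatments list of `list(label =, model_id =, params =)` truths.
#' @param n_flasks_per_treatment sample flasks per treatment.
#' @param n_blanks blank flasks (no substrate).
#' @param sampling_interval minutes between readings.
#' @param duration incubation length, hours.
#' @param noise_sd sd of the cumulative-scale measurement noise,
#'   mL/100 mg DM.
#' @param blank_drift_sd scale of the non-negative background gas drift
#'   shared by all flasks, mL (raw flask scale).
#' @param mass_mg incubated dry matter per flask, mg.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(treatments = NULL,
                              n_flasks_per_treatment = 6,
                              n_blanks = 3,
                              sampling_interval = 5,
                              duration = 24,
                              noise_sd = 0.1,
                              blank_drift_sd = 0.05,
                              mass_mg = 500,
                              seed = 1L) {
  if (is.null(treatments)) {
    ref <- reference_richards_fits()
    treatments <- lapply(seq_len(nrow(ref)), function(i)
      list(label = sprintf("%d%%", ref$inclusion[i]),
           model_id = "richards",
           params = c(A = ref$A[i], B = ref$B[i], C = ref$C[i], D = ref$D[i])))
  }
  n_steps <- duration * 60 / sampling_interval
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("duration must be an integer multiple of the sampling interval")
  stopifnot(noise_sd >= 0, blank_drift_sd >= 0, mass_mg > 0,
            n_flasks_per_treatment >= 0, n_blanks >= 0)
  for (tr in treatments)
    validate_params(gas_model(tr$model_id), tr$params)
  structure(
    list(treatments = treatments,
         n_flasks_per_treatment = n_flasks_per_treatment,
         n_blanks = n_blanks,
         sampling_interval = sampling_interval,
         duration = duration,
         noise_sd = noise_sd,
         blank_drift_sd = blank_drift_sd,
         mass_mg = mass_mg,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Reading times of an experiment configuration
#' @param config an [experiment_config()].
#' @return hours, `0, interval, ..., duration` (includes t = 0).
#' @export
config_time_grid <- function(config) {
  seq(0, config$duration, by = config$sampling_interval / 60)
}

#' Simulate one flask's cumulative gas series
#'
#' Evaluates the kinetic truth on the grid, perturbs the per-interval
#' increments with truncated Gaussian noise and re-accumulates, so the
#' returned series is non-decreasing. `noise_sd = 0` returns the closed
#' form exactly. Units are those of `params` (mL/100 mg DM for the
#' default truths).
#'
#' @param model_id kinetic model id.
#' @param params truth parameters (validated).
#' @param times reading grid, hours.
#' @param noise_sd cumulative-scale noise sd (see package details).
#' @param seed optional seed applied before drawing.
#' @return numeric cumulative gas series, one value per time.
#' @export
generate_flask <- function(model_id, params, times, noise_sd = 0, seed = NULL) {
  model <- as_gas_model(model_id)
  params <- validate_params(model, params)
  check_times(times)
  if (!is.null(seed)) set.seed(seed)
  truth <- model_value(model$model_id, params, times)
  if (noise_sd == 0 || length(times) < 2) return(truth)
  inc <- diff(truth)
  sd_inc <- noise_sd / sqrt(length(inc))
  noisy <- pmax(0, inc + stats::rnorm(length(inc), 0, sd_inc))
  truth[1] + cumsum(c(0, noisy))
}

# Non-negative background drift shared in expectation by sample and blank
# flasks (gas from microbial activity on the inoculum alone), raw-mL scale.
drift_series <- function(n_times, drift_sd) {
  if (drift_sd == 0 || n_times < 2) return(numeric(n_times))
  inc <- pmax(0, stats::rnorm(n_times - 1, 0, drift_sd / sqrt(n_times - 1)))
  c(0, cumsum(inc))
}

#' Simulate a full gas-production experiment
#'
#' Generates the long-format raw table: per-treatment sample flasks
#' (kinetic truth scaled to raw mL for the incubated mass, plus increment
#' noise, plus a background drift) and blank flasks (background drift
#' only). Output is deterministic given the config seed.
#'
#' @param config an [experiment_config()].
#' @return data.frame of class `raw_gas_table` with columns `treatment`,
#'   `flask`, `is_blank`, `time_h`, `gas` (raw mL per flask) and the
#'   config attached as attribute `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  times <- config_time_grid(config)
  scale <- config$mass_mg / 100          # per-100mg units -> raw flask mL
  rows <- list()
  for (tr in config$treatments) {
    for (f in seq_len(config$n_flasks_per_treatment)) {
      series <- generate_flask(tr$model_id, tr$params, times,
                               config$noise_sd) * scale +
        drift_series(length(times), config$blank_drift_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = tr$label,
        flask = sprintf("%s_f%d", tr$label, f),
        is_blank = FALSE,
        time_h = times,
        gas = series
      )
    }
  }
  for (b in seq_len(config$n_blanks)) {
    rows[[length(rows) + 1L]] <- data.frame(
      treatment = "blank",
      flask = sprintf("blank_%d", b),
      is_blank = TRUE,
      time_h = times,
      gas = drift_series(length(times), config$blank_drift_sd)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(), flask = character(),
               is_blank = logical(), time_h = numeric(), gas = numeric())
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("raw_gas_table", "data.frame")
  out
}

#' Blank-correct raw flask series and normalize to incubated mass
#'
#' Subtracts the pointwise mean of the blank flasks from every sample
#' flask and converts raw mL to mL per 100 mg incubated DM (division by
#' `mass_mg / 100`, i.e. by 5 for the standard 500 mg).
#'
#' @param samples long table (rows with `is_blank = FALSE`) or a full
#'   `raw_gas_table` from [generate_experiment()].
#' @param blanks long table of blank flasks; defaults to the blank rows
#'   of `samples`.
#' @param mass_mg incubated dry matter, mg (> 0).
#' @return named list of [gas_curve()] objects, one per sample flask.
#' @export
blank_correct <- function(samples, blanks = NULL, mass_mg = 500) {
  if (mass_mg <= 0) stop("mass_mg must be > 0")
  if (is.null(blanks)) {
    blanks <- samples[samples$is_blank, , drop = FALSE]
  }
  if (!is.null(samples$is_blank))
    samples <- samples[!samples$is_blank, , drop = FALSE]
  if (nrow(blanks) == 0) stop("no blank flasks supplied")
  if (nrow(samples) == 0) stop("no sample flasks supplied")
  grid <- sort(unique(samples$time_h))
  blank_mean <- tapply(blanks$gas, blanks$time_h, mean)
  if (!isTRUE(all.equal(as.numeric(names(blank_mean)), grid)))
    stop("blank and sample time grids are not aligned")
  scale <- mass_mg / 100
  flasks <- split(samples, samples$flask)
  curves <- lapply(flasks, function(fl) {
    fl <- fl[order(fl$time_h), , drop = FALSE]
    if (!isTRUE(all.equal(fl$time_h, grid)))
      stop("flask ", fl$flask[1], " is not on the common time grid")
    gas_curve(fl$time_h, (fl$gas - as.numeric(blank_mean)) / scale,
              treatment_id = as.character(fl$treatment[1]),
              replicate_id = as.character(fl$flask[1]))
  })
  curves[order(names(curves))]
}

#' Pointwise mean curve across flasks
#'
#' @param curves list of [gas_curve()] on a common grid.
#' @param treatment_id label for the averaged curve.
#' @return a [gas_curve()] of pointwise means.
#' @export
average_curve <- function(curves, treatment_id = "average") {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1]]$times
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, grid)))
      stop("curves are not on a common time grid")
  gas_curve(grid, rowMeans(sapply(curves, `[[`, "gas")),
            treatment_id = treatment_id, replicate_id = "mean")
}
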