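# Shared kinetic truths and curve builders for the suite.

# published per-treatment Richards truths (generator defaults)
ref_truths <- function() {
  ref <- reference_richards_fits()
  lapply(seq_len(nrow(ref)), function(i)
    c(A = ref$A[i], B = ref$B[i], C = ref$C[i], D = ref$D[i]))
}

# one representative valid parameter set per model family (average-curve
# published estimates)
model_truths <- list(
  gompertz = c(A = 5.03, B = 3.89, C = 0.19),
  orskov_mcdonald = c(A = -0.50, B = 7.48, C = 0.06),
  brody = c(A = 6.98, B = 1, C = 0.06),
  richards = c(A = 5.36, B = 1.03, C = 0.13, D = 2.03),
  dual_pool = c(A = 1.20, B = 0.25, C = 3.50, D = 3.76, E = 0.07)
)

five_min_grid <- function() seq(0, 24, by = 5 / 60)

noiseless_curve <- function(model_id, params, times = five_min_grid()) {
  gas_curve(times, gas_evaluate(model_id, params, times))
}

# central finite-difference Jacobian, the independent oracle
fd_jacobian <- function(model_id, params, times, h_rel = 1e-5) {
  sapply(seq_along(params), function(k) {
    h <- h_rel * max(1, abs(params[[k]]))
    up <- params; up[[k]] <- up[[k]] + h
    dn <- params; dn[[k]] <- dn[[k]] - h
    (gas_evaluate(model_id, up, times) - gas_evaluate(model_id, dn, times)) /
      (2 * h)
  })
}
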