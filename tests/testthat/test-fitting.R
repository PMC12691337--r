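test_that("default starts follow the data-driven heuristics", {
  cv <- gas_curve(0:23, seq(0.25, 6, length.out = 24) * 6 / 6)
  cv <- gas_curve(0:23, c(seq(0.1, 5.9, length.out = 23), 6))
  s <- default_start(cv, "richards")
  expect_equal(s, c(A = 6.3, B = 1, C = 0.1, D = 1.5))
  expect_equal(default_start(cv, "gompertz")[["B"]], 2)
  sd <- default_start(cv, "dual_pool")
  expect_equal(sd[["A"]] + sd[["D"]], 6.3)
  expect_equal(unname(sd[c("B", "C", "E")]), c(0.2, 2, 0.05))
  so <- default_start(cv, "orskov_mcdonald")
  expect_equal(so[["A"]], cv$gas[1])
  expect_error(default_start(gas_curve(0:9, rep(0, 10)), "brody"),
               "degenerate")
})

test_that("Gauss-Newton is a fixed point on noiseless data at the truth", {
  cv <- noiseless_curve("gompertz", model_truths$gompertz,
                        times = seq(0, 24, by = 1))
  f <- fit_gauss_newton(cv, "gompertz", start = model_truths$gompertz)
  expect_true(f$converged)
  expect_lte(f$n_iter, 2)
  expect_lt(f$sse, 1e-20)
})

test_that("Gauss-Newton recovers Brody truth from a perturbed start", {
  b <- model_truths$brody
  cv <- noiseless_curve("brody", b)
  f <- fit_gauss_newton(cv, "brody", start = b * 1.1)
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates - b) / abs(b)), 1e-4)
})

test_that("Levenberg-Marquardt recovers every published Richards truth", {
  for (truth in ref_truths()) {
    cv <- noiseless_curve("richards", truth)
    f <- fit_lm(cv, "richards")     # default data-driven start
    expect_true(f$converged)
    expect_lt(max(abs(f$estimates - truth) / abs(truth)), 1e-3)
  }
})

test_that("noiseless round trip recovers all five model families", {
  for (m in names(model_truths)) {
    cv <- noiseless_curve(m, model_truths[[m]])
    f <- fit_gas_model(cv, m)
    expect_true(f$converged, label = m)
    expect_lt(max(abs(f$estimates - model_truths[[m]]) /
                    abs(model_truths[[m]])), 1e-3)
  }
})

test_that("a rank-deficient curve yields a non-convergent result, no crash", {
  cv <- gas_curve(rep(12, 6), rep(3, 6))
  f <- fit_lm(cv, "richards")
  expect_false(f$converged)
  g <- fit_gauss_newton(cv, "gompertz")
  expect_false(g$converged)
})

test_that("algorithm dispatch follows the fitting policy", {
  cvr <- noiseless_curve("richards", model_truths$richards,
                         times = seq(0, 24, by = 0.5))
  expect_equal(fit_gas_model(cvr, "richards")$algorithm, "levenberg_marquardt")
  cvg <- noiseless_curve("gompertz", model_truths$gompertz,
                         times = seq(0, 24, by = 0.5))
  expect_equal(fit_gas_model(cvg, "gompertz")$algorithm, "gauss_newton")
  # Gauss-Newton starved of iterations from a distant start fails over to LM
  far <- c(A = 40, B = 30, C = 2)
  f <- fit_gas_model(cvg, "gompertz", start = far, max_iter_gn = 2)
  expect_equal(f$algorithm, "levenberg_marquardt")
  expect_true(f$converged)
})

test_that("SSE never increases across accepted iterations", {
  set.seed(41)
  tt <- seq(0, 24, by = 0.5)
  for (m in c("gompertz", "richards", "dual_pool")) {
    y <- gas_evaluate(m, model_truths[[m]], tt) + rnorm(length(tt), 0, 0.1)
    cv <- gas_curve(tt, y)
    f <- fit_gas_model(cv, m)
    expect_true(all(diff(f$sse_trace) <= 0), label = paste("trace", m))
  }
})

test_that("fitted SSE beats a dense brute-force grid search", {
  set.seed(13)
  truth <- c(A = 6, B = 3, C = 0.2)
  tt <- seq(0, 24, length.out = 18)
  y <- gas_evaluate("gompertz", truth, tt) + rnorm(18, 0, 0.15)
  cv <- gas_curve(tt, y)
  f <- fit_gas_model(cv, "gompertz")
  grid_sse <- Inf
  for (A in seq(3, 9, length.out = 21))
    for (B in seq(1.5, 4.5, length.out = 21))
      for (C in seq(0.1, 0.3, length.out = 21)) {
        s <- sum((y - gas_evaluate("gompertz", c(A = A, B = B, C = C), tt))^2)
        grid_sse <- min(grid_sse, s)
      }
  expect_true(f$converged)
  expect_lte(f$sse, grid_sse)
})

test_that("refitting from the returned optimum reproduces it", {
  set.seed(5)
  tt <- seq(0, 24, by = 0.5)
  y <- gas_evaluate("richards", model_truths$richards, tt) +
    rnorm(length(tt), 0, 0.08)
  cv <- gas_curve(tt, y)
  f1 <- fit_gas_model(cv, "richards")
  f2 <- fit_gas_model(cv, "richards", start = f1$estimates)
  expect_true(f2$converged)
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-6)
  expect_lte(f2$sse, f1$sse * (1 + 1e-10))
})

test_that("estimates agree with an independent LM implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(99)
  tt <- seq(0, 24, by = 0.5)
  truth <- model_truths$gompertz
  y <- gas_evaluate("gompertz", truth, tt) + rnorm(length(tt), 0, 0.1)
  cv <- gas_curve(tt, y)
  ours <- fit_gas_model(cv, "gompertz")
  ref <- minpack.lm::nlsLM(y ~ A * exp(-B * exp(-C * t)),
                           data = data.frame(t = tt, y = y),
                           start = as.list(default_start(cv, "gompertz")))
  expect_equal(unname(ours$estimates), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(ours$sse, sum(residuals(ref)^2), tolerance = 1e-8)
  # and the standard errors from (J'J)^-1 SSE/(n-p) match nls's
  expect_equal(unname(ours$std_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("curve validation flags suspicious blank-corrected data", {
  expect_warning(gas_curve(0:9, c(-0.8, seq(0.5, 4.5, length.out = 9))),
                 "-0.5")
  expect_error(gas_curve(0:3, 1:3), "equal length")
  expect_error(gas_curve(c(0, 1, NA), c(1, 2, 3)), "finite")
  expect_error(fit_lm(gas_curve(0:3, c(0, 1, 2, 3)), "dual_pool"),
               "fewer observations")
})
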