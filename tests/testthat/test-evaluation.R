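test_that("Gaussian AIC has the stated closed form", {
  n <- 120
  expect_equal(aic_gaussian(sse = n, n_obs = n, n_params = 4), 2 * 5)
  # equal SSE, one extra parameter: exactly +2
  expect_equal(aic_gaussian(10, 50, 4) - aic_gaussian(10, 50, 3), 2)
  # halving the SSE at n = 289 with one extra parameter
  d <- aic_gaussian(20, 289, 3) - aic_gaussian(10, 289, 4)
  expect_equal(d, 289 * log(2) - 2, tolerance = 1e-12)
  expect_warning(expect_identical(aic_gaussian(0, 10, 3), -Inf), "perfect")
  expect_error(aic_gaussian(5, 3, 4))
})

test_that("predicted-on-observed R2 is the squared correlation", {
  o <- c(1, 2, 3, 4)
  expect_equal(r2_pred_obs(o, o), 1)
  expect_equal(r2_pred_obs(2 * o + 3, o), 1)
  p <- c(1.1, 1.9, 3.2, 3.8)
  # independent oracle: direct correlation formula
  r_direct <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(r2_pred_obs(p, o), r_direct^2, tolerance = 1e-14)
  expect_equal(r2_pred_obs(p, o), summary(lm(p ~ o))$r.squared,
               tolerance = 1e-12)
  expect_error(r2_pred_obs(rep(1, 4), o), "constant")
})

test_that("CCC matches its definition and closed forms", {
  o <- c(1, 2, 3, 4, 6)
  expect_equal(ccc(o, o), 1)
  # constant shift c: 2v / (2v + c^2) with population variance v
  v <- var(o) * (length(o) - 1) / length(o)
  expect_equal(ccc(o + 2, o), 2 * v / (2 * v + 4), tolerance = 1e-14)
  set.seed(3)
  p <- rnorm(40); q <- p + rnorm(40, 0.3, 0.7)
  n <- 40
  brute <- 2 * mean((p - mean(p)) * (q - mean(q))) /
    (mean((p - mean(p))^2) + mean((q - mean(q))^2) + (mean(p) - mean(q))^2)
  expect_equal(ccc(p, q), brute, tolerance = 1e-12)
  # |CCC| never exceeds |Pearson correlation|
  expect_lte(abs(ccc(p, q)), abs(cor(p, q)))
  expect_error(ccc(rep(2, 5), o[1:5]), "constant")
})

test_that("MSPE decomposition conserves the total and isolates biases", {
  o <- c(1, 2, 3, 5, 8)
  m0 <- mspe(o, o)
  expect_equal(unlist(m0), c(mspe = 0, mean_bias = 0,
                             systematic_bias = 0, random_error = 0))
  # pure shift: everything in the mean-bias component
  ms <- mspe(o - 1.5, o)
  expect_equal(ms$mspe, 1.5^2)
  expect_equal(ms$mean_bias, 1.5^2)
  expect_equal(ms$systematic_bias + ms$random_error, 0, tolerance = 1e-14)
  set.seed(8)
  p <- rnorm(60, 5, 2); q <- 0.8 * p + rnorm(60, 1, 0.5)
  m <- mspe(p, q)
  expect_equal(m$mspe, mean((q - p)^2), tolerance = 1e-14)
  expect_equal(m$mean_bias + m$systematic_bias + m$random_error, m$mspe,
               tolerance = 1e-10 * m$mspe)
  expect_true(all(unlist(m) >= 0))
  expect_error(mspe(1:4, 1:5), "equal length")
})

test_that("evidence ratios follow exp(dAIC/2) and are monotone", {
  expect_equal(evidence_ratio(100, 100), 1)
  expect_equal(evidence_ratio(102, 100), exp(1))
  da <- seq(0, 30, by = 1.5)
  er <- sapply(da, function(d) evidence_ratio(100 + d, 100))
  expect_true(all(diff(er) > 0))
  expect_true(all(er >= 1))
  expect_error(evidence_ratio(99, 100), ">=")
})

test_that("paired-MSPE test handles degenerate and standard cases", {
  e <- c(0.3, -0.2, 0.5, -0.1)
  expect_equal(paired_mspe_test(e, e), 1)
  expect_error(paired_mspe_test(c(1, 1, 1), c(0, 0, 0)), "degenerate")
  set.seed(12)
  a <- rnorm(200); b <- rnorm(200, 0, 2)
  expect_lt(paired_mspe_test(a, b), 0.05)
})

test_that("paired-MSPE test is calibrated and has power", {
  # type-I: exchangeable errors, nominal 5% +/- 2 points over 1000 reps
  set.seed(2718)
  p0 <- replicate(1000, {
    a <- rnorm(100); b <- rnorm(100)
    paired_mspe_test(a, b)
  })
  expect_gt(mean(p0 < 0.05), 0.03)
  expect_lt(mean(p0 < 0.05), 0.07)
  # power at variance ratio 4, n = 200: reject in >= 95% of 500 reps
  set.seed(314)
  p1 <- replicate(500, {
    a <- rnorm(200, 0, 1); b <- rnorm(200, 0, 2)
    paired_mspe_test(a, b)
  })
  expect_gte(mean(p1 < 0.05), 0.95)
})

test_that("rank_models builds the adequacy table and picks lowest AIC", {
  set.seed(21)
  tt <- seq(0, 24, by = 5 / 60)
  truth <- c(A = 6.18, B = 0.97, C = 0.17, D = 1.99)
  cv <- gas_curve(tt, gas_evaluate("richards", truth, tt) +
                    rnorm(length(tt), 0, 0.1))
  fits <- lapply(c("gompertz", "brody", "richards"), fit_gas_model, curve = cv)
  rk <- rank_models(fits, cv)
  expect_equal(rk$best_model, "richards")
  expect_equal(rk$report$evidence_ratio[rk$report$model_id == "richards"], 1)
  expect_true(all(rk$report$evidence_ratio >= 1, na.rm = TRUE))
  pm <- rk$pmspe_pvalues
  expect_equal(pm, t(pm))
  expect_equal(unname(diag(pm)), rep(1, 3))
  expect_error(rank_models(fits[1], cv), "at least 2")
})

test_that("identical fits compare as indistinguishable", {
  tt <- seq(0, 24, by = 0.5)
  set.seed(4)
  cv <- gas_curve(tt, gas_evaluate("gompertz", model_truths$gompertz, tt) +
                    rnorm(length(tt), 0, 0.05))
  f <- fit_gas_model(cv, "gompertz")
  rk <- rank_models(list(f, f), cv)
  expect_equal(rk$report$evidence_ratio, c(1, 1))
  expect_equal(rk$pmspe_pvalues[1, 2], 1)
})

test_that("AIC ranking selects the generating Richards model most of the time", {
  set.seed(63)
  tt <- seq(0, 24, by = 0.25)
  truth <- c(A = 6.18, B = 0.97, C = 0.17, D = 1.99)
  mu <- gas_evaluate("richards", truth, tt)
  wins <- replicate(20, {
    cv <- gas_curve(tt, mu + rnorm(length(tt), 0, 0.1))
    fits <- lapply(c("gompertz", "brody", "richards"), fit_gas_model,
                   curve = cv)
    rank_models(fits, cv)$best_model == "richards"
  })
  expect_gt(mean(wins), 0.5)
})
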