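test_that("block-mean downsampling preserves DC and averages blocks", {
  expect_equal(downsample(trace(rep(1, 800), 80000), 20000)$values, rep(1, 200))
  alt <- trace(rep(c(1, -1, 1, -1) + 1, 200), 80000)   # mean 1 per block of 4
  expect_equal(downsample(alt, 20000)$values, rep(1, 200))
  expect_error(downsample(trace(1:100, 30000), 20000), "integer")
})

test_that("downsampling 80 to 20 kHz leaves a sub-millisecond tau unchanged", {
  p <- list(c = 0.65, k = 0.35, lambda = -1 / 0.00054, t0 = 0.05)
  hi <- gen_step_trace(p, rate = 80000, duration = 0.3, noise_sd = 0.002, seed = 3)
  lo <- downsample(hi, 20000)
  f_hi <- fit_exp_onset(hi, onset = 0.05, window = c(-0.05, 0.25))
  f_lo <- fit_exp_onset(lo, onset = 0.05, window = c(-0.05, 0.25))
  expect_equal(f_lo$tau_fast, f_hi$tau_fast, tolerance = 0.01)
})

test_that("noiseless mono fits recover all coefficients to high precision", {
  p <- list(c = 1, k = -0.2, lambda = -1 / 0.0012, t0 = 0.1)
  tr <- gen_step_trace(p, rate = 20000, duration = 1.1, noise_sd = 0, seed = 1)
  f <- fit_exp_onset(tr, onset = 0.1, model_order = 1)
  expect_false(f$degenerate)
  expect_equal(f$c, 1, tolerance = 1e-6)
  expect_equal(f$k, -0.2, tolerance = 1e-6)
  expect_equal(f$lambda, -1 / 0.0012, tolerance = 1e-6)
  expect_equal(f$t0, 0.1, tolerance = 1e-6)
  expect_equal(f$tau_fast, 1.2, tolerance = 1e-6)
})

test_that("fit residuals are orthogonal to the model basis at the optimum", {
  p <- list(c = 1, k = -0.2, lambda = -1 / 0.0012, t0 = 0.1)
  tr <- gen_step_trace(p, rate = 20000, duration = 1.1, noise_sd = 0.01, seed = 6)
  f <- fit_exp_onset(tr, onset = 0.1, model_order = 1)
  tt <- f$data$time
  post <- tt > f$t0
  e1 <- rep(1, length(tt)); e1[post] <- exp((tt[post] - f$t0) * f$lambda)
  r <- residuals(f)
  expect_lt(abs(sum(r * e1)) / (sqrt(sum(r^2)) * sqrt(sum(e1^2))), 1e-10)
  expect_lt(abs(sum(r)) / (sqrt(sum(r^2)) * sqrt(length(r))), 1e-10)
})

test_that("flat traces are flagged degenerate with undefined tau", {
  tr <- gen_step_trace(list(c = 1, k = 0, lambda = -100, t0 = 0.1),
                       rate = 5000, duration = 0.5, noise_sd = 1e-3, seed = 2)
  f <- fit_exp_onset(tr, onset = 0.1, window = c(-0.1, 0.4))
  expect_true(f$degenerate)
  expect_true(is.na(f$tau_fast))
  expect_error(summarize_time_constants(f), "degenerate")
})

test_that("time-shifting a trace shifts only the fitted onset", {
  p <- list(c = 1, k = -0.2, lambda = -1 / 0.002, t0 = 0.1)
  tr1 <- gen_step_trace(p, rate = 10000, duration = 0.6, noise_sd = 0, seed = 1)
  p2 <- p; p2$t0 <- 0.15
  tr2 <- gen_step_trace(p2, rate = 10000, duration = 0.6, noise_sd = 0, seed = 1)
  f1 <- fit_exp_onset(tr1, onset = 0.1, window = c(-0.08, 0.4))
  f2 <- fit_exp_onset(tr2, onset = 0.15, window = c(-0.08, 0.4))
  expect_equal(f2$t0 - f1$t0, 0.05, tolerance = 1e-6)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-5)
  expect_equal(f2$k, f1$k, tolerance = 1e-6)
  expect_equal(f2$c, f1$c, tolerance = 1e-6)
})

test_that("the independent nonlinear solver agrees with the variable-projection fitter", {
  p <- list(c = 0.65, k = 0.3126, k2 = 0.0375, lambda = -1 / 0.00054,
            lambda2 = -1 / 0.0103, t0 = 0.1)
  tr <- gen_step_trace(p, rate = 20000, duration = 1.1, noise_sd = 0.005, seed = 13)
  f <- fit_exp_onset(tr, onset = 0.1, model_order = 2)
  tt <- trace_times(tr); y <- tr$values
  ref <- minpack.lm::nlsLM(
    y ~ cc + (kk * exp((tt - tq) * ll) + k2 * exp((tt - tq) * l2)) * (tt > tq) +
      (kk + k2) * (tt <= tq),
    start = list(cc = 0.65, kk = 0.31, k2 = 0.04, ll = -1800, l2 = -100,
                 tq = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  rc <- coef(ref)
  expect_equal(f$lambda, unname(rc["ll"]), tolerance = 0.02)
  expect_equal(f$lambda2, unname(rc["l2"]), tolerance = 0.05)
  expect_equal(f$c, unname(rc["cc"]), tolerance = 1e-3)
})

test_that("time-constant summaries follow tau = -1000/lambda and amplitude fractions", {
  f <- structure(list(model_order = 2L, c = 1, k = -0.18, k2 = -0.02,
                      lambda = -500, lambda2 = -50, t0 = 0,
                      tau_fast = -1000 / -500, tau_slow = -1000 / -50,
                      frac_fast = 100 * 0.18 / 0.20, degenerate = FALSE),
                 class = "exp_onset_fit")
  s <- summarize_time_constants(f)
  expect_equal(s$tau_fast, 2.0)
  expect_equal(s$tau_slow, 20.0)
  expect_equal(s$frac_fast, 90.0)
})

test_that("dual fits order components so tau_fast <= tau_slow", {
  # generate with the 'fast' rate in the second slot: labels must swap
  p <- list(c = 0.7, k = 0.04, k2 = 0.26, lambda = -1 / 0.010,
            lambda2 = -1 / 0.0008, t0 = 0.05)
  tr <- gen_step_trace(p, rate = 20000, duration = 0.6, noise_sd = 0.002, seed = 5)
  f <- fit_exp_onset(tr, onset = 0.05, window = c(-0.05, 0.5), model_order = 2)
  expect_lte(f$tau_fast, f$tau_slow)
  expect_equal(f$tau_fast, 0.8, tolerance = 0.1)
  expect_equal(f$frac_fast, 100 * 0.26 / 0.30, tolerance = 3)
})

test_that("model selection prefers mono for mono data and dual for strong dual data", {
  mono <- gen_step_trace(list(c = 0.7, k = 0.3, lambda = -1 / 0.002, t0 = 0.05),
                         rate = 10000, duration = 0.6, noise_sd = 0.004, seed = 4)
  expect_equal(select_model(mono, onset = 0.05, window = c(-0.05, 0.5))$order, 1L)

  dual <- gen_step_trace(list(c = 0.65, k = 0.3, k2 = 0.05,
                              lambda = -1 / 0.001, lambda2 = -1 / 0.010,
                              t0 = 0.05),
                         rate = 10000, duration = 0.6, noise_sd = 0.002, seed = 4)
  expect_equal(select_model(dual, onset = 0.05, window = c(-0.05, 0.5))$order, 2L)

  # second component at the noise floor: parsimony wins
  weak <- gen_step_trace(list(c = 0.7, k = 0.3, k2 = 0.004,
                              lambda = -1 / 0.001, lambda2 = -1 / 0.010,
                              t0 = 0.05),
                         rate = 10000, duration = 0.6, noise_sd = 0.01, seed = 4)
  expect_equal(select_model(weak, onset = 0.05, window = c(-0.05, 0.5))$order, 1L)
})

test_that("baseline bleach correction flattens held-voltage segments", {
  tt <- seq(0, 4 - 1e-4, by = 1e-4)
  bleach <- 0.4 * exp(-0.8 * tt) + 0.6 * exp(-0.05 * tt)
  step <- ifelse(tt >= 1.5 & tt < 2.5, 0.8, 1)   # response away from baseline
  tr <- trace(1000 * bleach * step, 10000)
  corr <- correct_baseline_bleach(tr, baseline_windows = list(c(0, 1.4), c(2.6, 4)))
  base <- corr$values[tt < 1.4 | tt >= 2.6]
  expect_equal(base, rep(1, length(base)), tolerance = 1e-3)
  expect_error(correct_baseline_bleach(tr, list(c(0, 0.2))), "10%")
})

test_that("median tau_fast over seeded noisy replicates stays within 10% of truth", {
  p <- list(c = 0.65, k = 0.3126, k2 = 0.0375, lambda = -1 / 0.00054,
            lambda2 = -1 / 0.0103, t0 = 0.05)
  taus <- vapply(1:10, function(s) {
    tr <- gen_step_trace(p, rate = 10000, duration = 0.45, noise_sd = 0.01,
                         seed = 1000 + s)
    fit_exp_onset(tr, onset = 0.05, window = c(-0.05, 0.4),
                  model_order = 2)$tau_fast
  }, numeric(1))
  expect_lt(abs(stats::median(taus) - 0.54) / 0.54, 0.10)
})
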