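test_that("Welch PSD matches an independently computed reference spectrum", {
  n <- 2000; fs <- 200
  tt <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * tt) + 0.5 * cos(2 * pi * 20 * tt) + 0.25
  p <- welch_psd(trace(x, fs), nperseg = 256, overlap = 0.5)
  # reference values computed with an independent Welch implementation
  # (Hann window, 256-sample segments, 50% overlap, per-segment mean removal)
  i5 <- which.min(abs(p$freq - 4.6875))
  i20 <- which.min(abs(p$freq - 20.3125))
  expect_equal(p$power[i5], 0.3463475, tolerance = 1e-4)
  expect_equal(p$power[i20], 0.08658904, tolerance = 1e-4)
  expect_equal(psd_peak_freq(p), 4.6875)
})

test_that("Welch PSD satisfies Parseval and localises tones", {
  set.seed(30)
  w <- trace(rnorm(8000), 200)
  p <- welch_psd(w)
  expect_equal(sum(p$power) * p$df / var(w$values), 1, tolerance = 0.05)
  # white spectrum is flat: max/median bounded over many segments
  expect_lt(max(p$power) / median(p$power), 4)

  tone <- trace(sin(2 * pi * 5 * (0:3999) / 200), 200)
  expect_lt(abs(psd_peak_freq(welch_psd(tone)) - 5), 0.5)

  dc <- trace(rep(3, 1000) + 1e-9 * rnorm(1000), 200)
  pdc <- welch_psd(dc)
  expect_lt(sum(pdc$power[pdc$freq > 1]), 1e-12)
})

test_that("magnitude-squared coherence is bounded, reflexive, and scale-invariant", {
  set.seed(31)
  a <- trace(rnorm(4000), 200)
  self <- coherence(a, a)
  expect_equal(self$msc, rep(1, length(self$msc)), tolerance = 1e-9)

  b <- trace(rnorm(4000), 200)
  indep <- coherence(a, b)
  expect_true(all(indep$msc >= 0 & indep$msc <= 1))
  # bias bound for L independent segments: E[msc] ~ 1/L
  expect_lt(mean(indep$msc), 3 / indep$n_segments + 0.05)

  shared <- sin(2 * pi * 8 * (0:3999) / 200)
  x <- trace(shared + rnorm(4000, sd = 1), 200)
  y <- trace(shared + rnorm(4000, sd = 1), 200)
  co <- coherence(x, y)
  expect_equal(co$freq[which.max(co$msc)], 8, tolerance = 0.5)
  sc <- coherence(trace(5 * x$values, 200), trace(0.1 * y$values + 2, 200))
  expect_equal(sc$msc, co$msc, tolerance = 1e-9)
  expect_error(coherence(a, trace(rnorm(300), 200)), "length")
})

test_that("power-difference maps highlight the stimulated region only", {
  set.seed(32)
  n <- 4000; rate <- 200
  tt <- (0:(n - 1)) / rate
  stim <- tt >= 10 & tt < 18
  fr <- array(rnorm(n * 8 * 8, sd = 0.01), c(n, 8, 8))
  mod40 <- 0.2 * sin(2 * pi * 40 * tt) * stim
  for (i in 1:4) for (j in 1:4) fr[, i, j] <- fr[, i, j] + mod40
  mov <- movie(fr - min(fr), rate)
  pm <- power_difference_map(mov, 40, stim_window = c(10, 18),
                             baseline_window = c(0, 8), roi = 2)
  expect_equal(dim(pm$map), c(4, 4))
  inR <- pm$map[1:2, 1:2]; outR <- pm$map[3:4, 3:4]
  expect_gt(min(inR), 10 * max(abs(outR)))

  # no stimulation difference: map is near zero everywhere
  quiet <- movie(array(rnorm(n * 4 * 4, sd = 0.01) + 1, c(n, 4, 4)), rate)
  pm0 <- power_difference_map(quiet, 40, c(10, 18), c(0, 8), roi = 2)
  expect_lt(max(abs(pm0$map)), 1e-4)
  expect_lt(abs(mean(pm0$map)), 1e-5)

  # 60-Hz variant behaves identically at its own frequency
  mod60 <- 0.2 * sin(2 * pi * 60 * tt) * stim
  fr60 <- array(rnorm(n * 4 * 4, sd = 0.01), c(n, 4, 4))
  for (i in 1:2) for (j in 1:2) fr60[, i, j] <- fr60[, i, j] + mod60
  pm60 <- power_difference_map(movie(fr60 - min(fr60), rate), 60,
                               c(10, 18), c(0, 8), roi = 2)
  expect_gt(pm60$map[1, 1], 10 * max(abs(pm60$map[2, 2])))
  expect_error(power_difference_map(mov, 40, c(10, 10.2), c(0, 8)), "segment")
})

test_that("correlation maps are exact for copies and invariant to affine LFP scaling", {
  sim <- gen_dual_channel_movie(movie_sim_config(shape = c(4, 4), duration = 10),
                                seed = 8)
  res <- run_pipeline(sim$recording, run_config("anesthetized"),
                      bg_green = 100, bg_red = 100)
  lfp <- trace(res$corrected[, 1], res$rate)
  cm <- correlation_map(res, lfp)
  expect_equal(cm$map[1, 1], 1, tolerance = 1e-12)
  anti <- trace(-lfp$values, res$rate)
  expect_equal(correlation_map(res, anti)$map[1, 1], -1, tolerance = 1e-12)
  scaled <- trace(3.2 * lfp$values - 7, res$rate)
  expect_equal(correlation_map(res, scaled)$map, cm$map, tolerance = 1e-12)
})

test_that("the modal best channel finds the electrode carrying the shared source", {
  set.seed(33)
  sim <- gen_dual_channel_movie(movie_sim_config(shape = c(4, 4), duration = 10),
                                seed = 9)
  res <- run_pipeline(sim$recording, run_config("anesthetized"),
                      bg_green = 100, bg_red = 100)
  shared <- res$corrected[, 3]
  chans <- list(trace(rnorm(length(shared)), res$rate),
                trace(shared + rnorm(length(shared), sd = 0.3 * sd(shared)),
                      res$rate),
                trace(rnorm(length(shared)), res$rate))
  bc <- best_lfp_channel(res, chans)
  expect_equal(bc$modal_channel, 2L)
})

test_that("LFP conditioning applies inversion, decimation, lowpass, and notch in order", {
  rate <- 1000
  tt <- (0:9999) / rate
  raw <- trace(sin(2 * pi * 8 * tt) + 0.5 * sin(2 * pi * 60 * tt) +
                 0.5 * sin(2 * pi * 85 * tt), rate)
  cond <- condition_lfp(raw, target_rate = 200)
  expect_equal(cond$rate, 200)
  p <- welch_psd(cond)
  i8 <- which.min(abs(p$freq - 8))
  i60 <- which.min(abs(p$freq - 60))
  i85 <- which.min(abs(p$freq - 85))
  expect_gt(p$power[i8] / p$power[i60], 100)   # notch removed the hum
  expect_gt(p$power[i8] / p$power[i85], 100)   # lowpass removed 85 Hz
  # inversion: conditioned trace anti-correlates with the raw 8-Hz component
  d8 <- band_filter(downsample(raw, 200), c(4, 12))
  expect_lt(cor(cond$values, d8$values), -0.9)
})

test_that("shuffled controls are seeded derangements that break shared structure", {
  set.seed(34)
  n_tr <- 6; n <- 1000
  shared <- lapply(1:n_tr, function(i) rnorm(n))
  img <- lapply(1:n_tr, function(i)
    trace(shared[[i]] + rnorm(n, sd = 0.5), 200))
  lfp <- lapply(1:n_tr, function(i)
    trace(shared[[i]] + rnorm(n, sd = 0.5), 200))
  matched <- vapply(1:n_tr, function(i)
    cor(img[[i]]$values, lfp[[i]]$values), numeric(1))
  null <- shuffled_control(img, lfp, n_shuffles = 50, seed = 5)
  expect_gt(mean(matched), mean(null) + 3 * sd(null) / sqrt(length(null)))
  expect_identical(shuffled_control(img, lfp, 10, seed = 7),
                   shuffled_control(img, lfp, 10, seed = 7))
  expect_error(shuffled_control(img[1], lfp[1]), "2 matched trials")
})
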