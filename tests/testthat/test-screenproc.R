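test_that("background is the low-intensity mode and masks exclude saturated pixels", {
  set.seed(4)
  fr <- array(rnorm(10 * 16 * 16, mean = 100, sd = 2), c(10, 16, 16))
  fr[, 4:6, 4:6] <- 1000                      # a bright blob
  fr[, 5, 5] <- 4095                          # saturated core
  m <- movie(fr, 100, saturation_level = 4095)
  est <- estimate_background_and_mask(m)
  expect_lt(abs(est$background - 100), 2)
  g <- mask_grid(est$mask)
  expect_false(g[5, 5])                       # saturated pixel excluded
  expect_true(all(g[4:6, 4:6][-5]))           # rest of the blob selected
  expect_equal(sum(g), 8)
  expect_false(any(g[10:16, 10:16]))          # background stays out

  flat <- movie(array(100, c(5, 8, 8)), 100)
  expect_warning(est2 <- estimate_background_and_mask(flat), "empty")
  expect_equal(est2$background, 100)
  expect_equal(mask_size(est2$mask), 0)
})

test_that("responsive-mask selection equals the brute-force best batch prefix", {
  for (seed in c(3, 7, 21)) {
    fov <- gen_screen_fov(n_cells = 5, response_amp = -0.25,
                          frac_nonresponsive = 0.4, noise_sd = 0.02,
                          shape = c(24, 24), rate = 200, duration = 5,
                          seed = seed)
    est <- estimate_background_and_mask(fov$green)
    g_bs <- fov$green
    g_bs$frames <- g_bs$frames - est$background
    ev <- fov$protocol$events
    ex <- lapply(seq_len(nrow(ev)), function(i)
      c(ev$onset[i], ev$onset[i] + ev$duration[i] + 0.3))
    trend <- fit_trend(movie_trace(g_bs, est$mask), ex, n_terms = 3)
    gd <- detrend_divide(g_bs, trend, per_pixel = TRUE, mask = est$mask)
    sel <- select_responsive_mask(gd, est$mask, fov$protocol, batch = 40)
    oracle_pixels <- bf_best_prefix(gd, est$mask, fov$protocol, batch = 40)
    expect_setequal(which(mask_grid(sel$mask)), oracle_pixels)
    # selected-mask SNR is never below the full initial mask's
    expect_gte(sel$snr, sel$prefix_snr[length(sel$prefix_snr)])
  }
})

test_that("sub-batch masks and all-identical pixels hit the documented edges", {
  fov <- gen_screen_fov(n_cells = 2, response_amp = -0.2, noise_sd = 0.02,
                        shape = c(16, 16), rate = 200, duration = 5, seed = 2)
  est <- estimate_background_and_mask(fov$green)
  gd <- detrend_divide(fov$green, fit_trend(movie_trace(fov$green, est$mask),
                                            n_terms = 2),
                       per_pixel = TRUE, mask = est$mask)
  sel <- select_responsive_mask(gd, est$mask, fov$protocol, batch = 10000)
  expect_identical(mask_grid(sel$mask), mask_grid(est$mask))

  # identical pixels: every prefix ties, tie broken toward fewer batches
  n <- 400
  v <- 1 + c(rep(0, 150), rep(-0.2, 20), rep(0, n - 170))
  fr <- array(0, c(n, 6, 6))
  for (i in 1:6) for (j in 1:6) fr[, i, j] <- v
  mov <- movie(fr, 100)
  proto <- stimulus_protocol(onset = 1.5, duration = 0.2)
  sel2 <- select_responsive_mask(mov, pixel_mask(matrix(TRUE, 6, 6)), proto,
                                 batch = 6)
  expect_equal(mask_size(sel2$mask), 6)
})

test_that("response amplitude and width are exact on closed-form pulses", {
  n <- 1000
  v <- rep(1, n)
  v[401:440] <- 0.8                      # square -0.20 dip at t = 2.0-2.2 s
  tr <- trace(v, 200)
  proto <- stimulus_protocol(onset = 2.0, duration = 0.2)
  ra <- response_amplitude(tr, proto)
  expect_equal(ra$amplitude, -0.20)
  # two identical events give identical amplitudes
  v2 <- rep(1, n); v2[201:220] <- 0.85; v2[601:620] <- 0.85
  ra2 <- response_amplitude(trace(v2, 200),
                            stimulus_protocol(c(1, 3), duration = 0.1))
  expect_equal(ra2$amplitude[1], ra2$amplitude[2])
  expect_equal(ra2$amplitude[1], -0.15)
  # event running past the record end is an error
  expect_error(response_amplitude(tr, stimulus_protocol(4.9, duration = 0.2)),
               "truncated")
})

test_that("generator response amplitude is recovered through the screening chain", {
  fov <- gen_screen_fov(n_cells = 5, response_amp = -0.25,
                        frac_nonresponsive = 0, noise_sd = 0,
                        shape = c(32, 32), rate = 200, duration = 5, seed = 6)
  sm <- screen_fov(fov$green, fov$red_frame, fov$protocol, batch = 50)
  expect_equal(sm$response_amplitudes$amplitude,
               fov$truth$event_amplitudes, tolerance = 0.01)
})

test_that("brightness ratio is the masked mean ratio and scales homogeneously", {
  g <- matrix(200, 8, 8); r <- matrix(100, 8, 8)
  mk <- pixel_mask(matrix(TRUE, 8, 8))
  expect_equal(brightness_ratio(g, r, mk), 2.0)
  expect_equal(brightness_ratio(3 * g, r, mk), 6.0)
  expect_error(brightness_ratio(g, r * 0, mk), "not positive")
  expect_equal(combine_brightness(c(2, 4), c(100, 300)), 3.5)
  # invariant to adding the background back to both channels and re-subtracting
  bg <- 50
  expect_equal(brightness_ratio((g + bg) - bg, (r + bg) - bg, mk), 2.0)
})

test_that("photostability gives closed-form budgets and half-lives", {
  const <- trace(rep(1, 12000), 100)
  pm <- photostability_metrics(const)
  expect_equal(pm$photon_budget, 120)
  expect_true(is.na(pm$half_life))

  tt <- seq(0, 60, by = 0.01)
  pure <- trace(exp(-tt / 10), 100)
  pm2 <- photostability_metrics(pure)
  expect_equal(pm2$half_life, 10 * log(2), tolerance = 1e-4)

  # noisy 3-term curve: half-life within 2% of the generating curve's root
  gen <- function(t) 0.5 * exp(-t / 3) + 0.3 * exp(-t / 20) + 0.2 * exp(-t / 200)
  set.seed(8)
  noisy <- trace(gen(tt) + rnorm(length(tt), sd = 0.005), 100)
  pm3 <- photostability_metrics(noisy)
  root <- uniroot(function(t) gen(t) - 0.5, c(0.01, 60))$root
  expect_equal(pm3$half_life, root, tolerance = 0.02)

  # budget is monotone under pointwise-smaller traces
  smaller <- trace(pure$values * 0.9 + 0.0, 100, )
  expect_lt(photostability_metrics(smaller, tol = 0.2)$photon_budget,
            pm2$photon_budget)
  expect_error(photostability_metrics(trace(rep(0.5, 300), 100)), "normalized")
})

test_that("spectra processing applies blank subtraction, the 10% rule, and peak normalization", {
  wl <- 350:535
  shape <- function(center, width = 15) exp(-((wl - center)^2) / (2 * width^2))
  blank <- rep(5, length(wl))
  scans <- list(100 * shape(487) + blank,
                80 * shape(487) + blank,
                60 * shape(487) + blank + 15)   # 15/60 = 25% residual at 350 nm
  out <- process_spectra(wl, scans, blanks = list(blank))
  expect_equal(out$excluded, 3L)
  expect_equal(out$n_used, 2)
  expect_equal(out$peak_wavelength, 487)
  expect_equal(max(out$spectrum), 1)
  expect_equal(wl[which.max(out$spectrum)], 487)
  expect_error(process_spectra(wl, scans[3], blanks = list(blank)), "excluded")
})

test_that("light onset is the first frame above the steady-state threshold", {
  fr <- array(0, c(20, 4, 4))
  fr[6:20, , ] <- 1000
  expect_equal(detect_light_onset(movie(fr, 100)), 5L)
  # gradual ramp: earliest frame above threshold
  fr2 <- array(0, c(20, 4, 4)); fr2[5, , ] <- 400; fr2[6:20, , ] <- 1000
  expect_equal(detect_light_onset(movie(fr2, 100), threshold_frac = 0.3), 4L)
  expect_warning(idx <- detect_light_onset(movie(array(1000, c(10, 4, 4)), 100)),
                 "bright")
  expect_equal(idx, 0L)
})
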