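#' Configuration for synthetic dual-channel widefield movies
#'
#' Describes the generative model for paired green (indicator) and red
#' (reference) movies: a shared heartbeat artifact (about 5 Hz in lightly
#' anesthetized mice, 10-14 Hz awake), slow hemodynamics, two-term exponential
#' photobleaching on the green channel, shared illumination noise, independent
#' sensor noise, and a voltage signal present only in the green channel.
#'
#' Artifact fractions are not published for real recordings; the defaults here
#' (5% heartbeat, 2% slow hemodynamics, 0.5% shared illumination noise, 1%
#' sensor noise, 2% voltage signal) are fixed, documented study conditions.
#'
#' @param shape `c(rows, cols)` of the frame (default 16 x 16).
#' @param rate Frame rate in Hz (default 200).
#' @param duration Trial length in seconds (default 20).
#' @param mode `"anesthetized"` (heartbeat 5 Hz) or `"awake"` (12 Hz).
#' @param heartbeat_hz Heartbeat frequency in Hz; default set by `mode`.
#' @param heartbeat_amp Fractional heartbeat amplitude in the green channel
#'   (default 0.05); the red channel carries it with gain `heartbeat_red_gain`.
#' @param heartbeat_red_gain Red/green heartbeat gain ratio (default 1.3).
#' @param slow_hemo_band Frequency band of slow hemodynamics, Hz (default
#'   0.1-1).
#' @param slow_hemo_amp Fractional sd of the slow hemodynamic component
#'   (default 0.02).
#' @param bleach_params `c(A1, lambda1, A2, lambda2)` of the green-channel
#'   two-term exponential bleach, rates in 1/s (< 0); amplitudes should sum to
#'   1 so the bleach curve starts at 1.
#' @param voltage_amp Fractional sd of the default broadband (0.5-10 Hz)
#'   voltage signal (default 0.02).
#' @param voltage_signal Optional [trace] of fractional dF/F to embed instead
#'   of the default broadband signal; must match `rate` and `duration`.
#' @param shared_noise_sd Fractional sd of illumination noise common to both
#'   channels (default 0.005).
#' @param independent_noise_sd Fractional sd of per-channel sensor noise
#'   (default 0.01).
#' @param background_level Dark background counts (default 100).
#' @param green_brightness,red_brightness Foreground brightness in counts
#'   (defaults 1000, 800).
#' @return An object of class `movie_sim_config`.
#' @export
movie_sim_config <- function(shape = c(16, 16), rate = 200, duration = 20,
                             mode = c("anesthetized", "awake"),
                             heartbeat_hz = NULL, heartbeat_amp = 0.05,
                             heartbeat_red_gain = 1.3,
                             slow_hemo_band = c(0.1, 1), slow_hemo_amp = 0.02,
                             bleach_params = c(0.1, -0.2, 0.9, -1 / 300),
                             voltage_amp = 0.02, voltage_signal = NULL,
                             shared_noise_sd = 0.005,
                             independent_noise_sd = 0.01,
                             background_level = 100,
                             green_brightness = 1000, red_brightness = 800) {
  mode <- match.arg(mode)
  if (is.null(heartbeat_hz))
    heartbeat_hz <- if (mode == "anesthetized") 5 else 12
  if (heartbeat_hz >= rate / 2)
    stop("Nyquist violation: heartbeat_hz must be below rate/2")
  if (heartbeat_amp < 0 || heartbeat_amp >= 1 || slow_hemo_amp < 0 || slow_hemo_amp >= 1)
    stop("fractional amplitudes must be in [0, 1)")
  if (any(bleach_params[c(2, 4)] >= 0)) stop("bleach rates must be negative")
  structure(list(shape = shape, rate = rate, duration = duration, mode = mode,
                 heartbeat_hz = heartbeat_hz, heartbeat_amp = heartbeat_amp,
                 heartbeat_red_gain = heartbeat_red_gain,
                 slow_hemo_band = slow_hemo_band, slow_hemo_amp = slow_hemo_amp,
                 bleach_params = bleach_params, voltage_amp = voltage_amp,
                 voltage_signal = voltage_signal,
                 shared_noise_sd = shared_noise_sd,
                 independent_noise_sd = independent_noise_sd,
                 background_level = background_level,
                 green_brightness = green_brightness,
                 red_brightness = red_brightness),
            class = "movie_sim_config")
}

# band-limited Gaussian noise, unit sd (0 if amp would be 0-length record)
bandlimited_noise <- function(n, rate, band) {
  x <- stats::rnorm(n)
  y <- butter_filtfilt(x, rate, "pass", band, order = 4)
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

# heartbeat: sinusoid with slow random-walk frequency jitter (+-5%) and mild
# amplitude modulation, so it is a narrowband artifact rather than a pure tone
heartbeat_component <- function(n, rate, f0) {
  jit <- cumsum(stats::rnorm(n, sd = 0.02 / sqrt(rate)))
  jit <- pmax(-0.05, pmin(0.05, jit))
  finst <- f0 * (1 + jit)
  phase <- cumsum(2 * pi * finst / rate)
  am <- 1 + 0.1 * butter_filtfilt(stats::rnorm(n), rate, "low", 0.5, order = 2)
  am * sin(phase)
}

#' Generate a synthetic dual-channel widefield recording
#'
#' Composes `green = background + bleach(t) * brightness * (1 + voltage +
#' artifacts + shared noise) + sensor noise` and `red = background + brightness
#' * (1 + artifacts + shared noise) + sensor noise`. The heartbeat and slow
#' hemodynamics appear in both channels (with a per-channel gain); the voltage
#' signal appears only in the green channel. Identical `(cfg, seed)` give
#' bit-identical output.
#'
#' @param cfg A [movie_sim_config].
#' @param seed Integer seed.
#' @return A list with `recording` (a [dual_channel_recording]) and `truth`, a
#'   list holding the clean fractional voltage trace, the artifact components,
#'   the bleach curve, and a `clipped` flag (TRUE if any composed intensity
#'   fell below zero and was clipped).
#' @export
gen_dual_channel_movie <- function(cfg = movie_sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "movie_sim_config"))
  set.seed(seed)
  n <- round(cfg$duration * cfg$rate)
  tt <- (0:(n - 1)) / cfg$rate

  hb <- cfg$heartbeat_amp * heartbeat_component(n, cfg$rate, cfg$heartbeat_hz)
  sh <- if (cfg$slow_hemo_amp > 0)
    cfg$slow_hemo_amp * bandlimited_noise(n, cfg$rate, cfg$slow_hemo_band)
  else numeric(n)
  if (is.null(cfg$voltage_signal)) {
    v <- if (cfg$voltage_amp > 0)
      cfg$voltage_amp * bandlimited_noise(n, cfg$rate, c(0.5, 10))
    else numeric(n)
  } else {
    stopifnot(inherits(cfg$voltage_signal, "trace"))
    if (length(cfg$voltage_signal$values) != n || cfg$voltage_signal$rate != cfg$rate)
      stop("voltage_signal must match the configured rate and duration")
    v <- cfg$voltage_signal$values
  }
  shared <- if (cfg$shared_noise_sd > 0) cfg$shared_noise_sd * stats::rnorm(n)
            else numeric(n)
  bp <- cfg$bleach_params
  bleach <- bp[1] * exp(bp[2] * tt) + bp[3] * exp(bp[4] * tt)

  npix <- cfg$shape[1] * cfg$shape[2]
  g_common <- cfg$background_level +
    bleach * cfg$green_brightness * (1 + v + hb + sh + shared)
  r_common <- cfg$background_level +
    cfg$red_brightness * (1 + cfg$heartbeat_red_gain * (hb + sh) + shared)

  g_flat <- matrix(g_common, nrow = n, ncol = npix) +
    matrix(stats::rnorm(n * npix, sd = cfg$independent_noise_sd * cfg$green_brightness),
           nrow = n)
  r_flat <- matrix(r_common, nrow = n, ncol = npix) +
    matrix(stats::rnorm(n * npix, sd = cfg$independent_noise_sd * cfg$red_brightness),
           nrow = n)

  clipped <- min(g_flat) < 0 || min(r_flat) < 0
  if (clipped) {
    warning("negative intensities after composition were clipped to 0")
    g_flat[g_flat < 0] <- 0
    r_flat[r_flat < 0] <- 0
  }
  dims <- c(n, cfg$shape)
  rec <- dual_channel_recording(
    movie(array(g_flat, dims), cfg$rate, "green"),
    movie(array(r_flat, dims), cfg$rate, "red"),
    trial_id = sprintf("synth-%s-seed%d", cfg$mode, seed),
    metadata = list(mode = cfg$mode, seed = seed)
  )
  truth <- list(voltage = trace(v, cfg$rate, units = "dF/F"),
                heartbeat = trace(hb, cfg$rate, units = "dF/F"),
                slow_hemo = trace(sh, cfg$rate, units = "dF/F"),
                shared_noise = trace(shared, cfg$rate, units = "dF/F"),
                bleach = trace(bleach, cfg$rate, units = "norm"),
                clipped = clipped)
  list(recording = rec, truth = truth)
}
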