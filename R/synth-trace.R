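#' Generate a step-response fluorescence trace from the onset-exponential model
#'
#' The noiseless part follows the exponential-with-onset model exactly: the
#' trace is constant at `c + k` (mono) or `c + k + k2` (dual) up to the onset
#' `t0` and relaxes exponentially toward the plateau `c` afterwards. Gaussian
#' noise of the requested sd is added.
#'
#' @param model_params Named list with `c`, `k`, `lambda`, `t0` and optionally
#'   `k2`, `lambda2` (dual model). Rates `lambda` are 1/s and must be
#'   negative; `tau = -1/lambda`.
#' @param rate Sampling rate in Hz (default 20000).
#' @param duration Record length in seconds; `t0` must lie inside it.
#' @param noise_sd Gaussian noise sd in trace units.
#' @param seed Integer seed.
#' @return A [trace].
#' @export
gen_step_trace <- function(model_params, rate = 20000, duration = 1.1,
                           noise_sd = 0, seed = 1L) {
  p <- model_params
  if (p$lambda >= 0) stop("lambda must be negative (decay toward the plateau)")
  if (!is.null(p$lambda2) && p$lambda2 >= 0) stop("lambda2 must be negative")
  if (p$t0 < 0 || p$t0 > duration) stop("t0 must lie within the record")
  set.seed(seed)
  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  y <- exp_onset_model(tt, p)
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  trace(y, rate, units = "norm F", polarity = "positive_up")
}

#' Generate a fluorescence trace with spike transients
#'
#' Negative-going Gaussian-shaped transients at given spike times, on top of an
#' optional slow drift and Gaussian noise, emulating the fluorescence of a
#' fast, negative-going voltage indicator during high-frequency firing.
#'
#' @param spike_times Sorted spike times (s) within the record.
#' @param amplitude Absolute transient amplitude (trace units).
#' @param width_fwhm Transient full width at half maximum (s); must be at
#'   least `2 / rate`.
#' @param noise_sd Gaussian noise sd.
#' @param drift_spec Optional list `list(amplitude=, freq_hz=)` adding a slow
#'   sinusoidal drift.
#' @param rate Sampling rate in Hz.
#' @param duration Record length (s).
#' @param baseline Baseline level (default 1).
#' @param seed Integer seed.
#' @return A list with `trace` (polarity `"negative_up"`) and `truth_times`
#'   (the generating spike times). Spikes closer than one FWHM are flagged via
#'   attribute `overlapping` on the result.
#' @export
gen_spike_trace <- function(spike_times, amplitude, width_fwhm, noise_sd = 0,
                            drift_spec = NULL, rate = 20000, duration = 1,
                            baseline = 1, seed = 1L) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  if (length(spike_times) && (min(spike_times) < 0 || max(spike_times) > duration))
    stop("spike_times must lie within the record")
  if (width_fwhm < 2 / rate) stop("width_fwhm must be at least 2 samples")
  overlapping <- length(spike_times) > 1 && any(diff(spike_times) < width_fwhm)
  if (overlapping) warning("spikes closer than one FWHM overlap")
  set.seed(seed)
  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  sigma <- width_fwhm / (2 * sqrt(2 * log(2)))
  y <- rep(baseline, n)
  for (ts in spike_times) {
    lo <- max(1, floor((ts - 5 * sigma) * rate)); hi <- min(n, ceiling((ts + 5 * sigma) * rate))
    idx <- lo:hi
    y[idx] <- y[idx] - amplitude * exp(-((tt[idx] - ts)^2) / (2 * sigma^2))
  }
  if (!is.null(drift_spec))
    y <- y + drift_spec$amplitude * sin(2 * pi * drift_spec$freq_hz * tt)
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  out <- list(trace = trace(y, rate, units = "norm F", polarity = "negative_up"),
              truth_times = spike_times)
  attr(out, "overlapping") <- overlapping
  out
}

#' Generate a screening field of view with responsive cells
#'
#' Disk-shaped cells on a dark background; a configurable fraction of cell
#' pixels is non-responsive (emulating over-expressing cells and fluorescent
#' debris), the rest carry stimulus-locked negative-going transients following
#' the protocol. A single-frame red reference proportional to the cell
#' footprint is generated alongside.
#'
#' @param n_cells Number of cells (>= 1).
#' @param response_amp Signed fractional response amplitude, in (-1, 1);
#'   negative for this indicator family.
#' @param efs_protocol A [stimulus_protocol]; default [efs_screen_protocol()].
#' @param bleach_params `c(A1, lambda1, A2, lambda2)`; rates < 0.
#' @param frac_nonresponsive Fraction of cell pixels without a response.
#' @param noise_sd Fractional sensor noise sd.
#' @param shape Frame shape (default 48 x 48).
#' @param rate Frame rate Hz (default 500).
#' @param duration Record length s (default 5).
#' @param seed Integer seed.
#' @return List with `green` ([movie]), `red_frame` (single-frame [movie]),
#'   `protocol`, and `truth` (cell mask, responsive mask, per-event
#'   amplitudes, background level).
#' @export
gen_screen_fov <- function(n_cells = 5, response_amp = -0.2,
                           efs_protocol = efs_screen_protocol(),
                           bleach_params = c(0.15, -0.5, 0.85, -1 / 100),
                           frac_nonresponsive = 0, noise_sd = 0.01,
                           shape = c(48, 48), rate = 500, duration = 5,
                           background_level = 100, brightness = 1000,
                           seed = 1L) {
  stopifnot(n_cells >= 1, abs(response_amp) < 1)
  set.seed(seed)
  n <- round(duration * rate)
  tt <- (0:(n - 1)) / rate
  radius <- max(2, round(min(shape) / 12))
  centers <- cbind(stats::runif(n_cells, radius + 1, shape[1] - radius),
                   stats::runif(n_cells, radius + 1, shape[2] - radius))
  if (any(centers < radius) || any(centers[, 1] > shape[1] - radius + 1) ||
      any(centers[, 2] > shape[2] - radius + 1))
    stop("cells exceed frame bounds")
  cell <- matrix(FALSE, shape[1], shape[2])
  rr <- row(cell); cc <- col(cell)
  for (i in seq_len(n_cells))
    cell <- cell | ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2)

  cell_idx <- which(cell)
  n_nonresp <- round(frac_nonresponsive * length(cell_idx))
  nonresp_idx <- if (n_nonresp > 0) sample(cell_idx, n_nonresp) else integer(0)
  resp <- cell; resp[nonresp_idx] <- FALSE

  # stimulus-locked response: flat at response_amp over the event, exponential
  # recovery (tau 50 ms) afterwards; peak |dF/F| equals |response_amp| exactly
  s <- numeric(n)
  ev <- efs_protocol$events
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]; off <- ev$onset[i] + max(ev$duration[i], 0.02)
    in_ev <- tt >= on & tt < off
    s[in_ev] <- response_amp
    rec <- tt >= off & tt < off + 0.3
    s[rec] <- response_amp * exp(-(tt[rec] - off) / 0.05)
  }
  bleach <- bleach_params[1] * exp(bleach_params[2] * tt) +
    bleach_params[3] * exp(bleach_params[4] * tt)

  npix <- prod(shape)
  flat <- matrix(background_level, nrow = n, ncol = npix)
  base <- bleach * brightness
  for (j in cell_idx) {
    sig <- if (j %in% nonresp_idx) rep(1, n) else 1 + s
    flat[, j] <- flat[, j] + base * sig
  }
  if (noise_sd > 0)
    flat <- flat + matrix(stats::rnorm(n * npix, sd = noise_sd * brightness), nrow = n)
  flat[flat < 0] <- 0

  red <- matrix(background_level, shape[1], shape[2])
  red[cell] <- red[cell] + 0.8 * brightness
  list(
    green = movie(array(flat, c(n, shape)), rate, "green"),
    red_frame = movie(array(red, c(1, shape)), rate, "red"),
    protocol = efs_protocol,
    truth = list(cell_mask = pixel_mask(cell),
                 responsive_mask = pixel_mask(resp),
                 event_amplitudes = rep(response_amp, nrow(ev)),
                 background_level = background_level,
                 bleach = trace(bleach, rate, units = "norm"))
  )
}
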