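# Spectral mapping: stimulation-frequency power-difference maps, LFP
# conditioning and correlation maps, and shuffled (trial-mismatch) controls.

#' Power-difference map at a target frequency
#'
#' For every ROI the short-time spectrogram power in the bin nearest the
#' target frequency is averaged within the stimulation window and within the
#' baseline window; the map is stimulation minus baseline, revealing regions
#' that follow the stimulation frequency (e.g. 40- or 60-Hz sensory trains).
#'
#' @param movie_corrected A corrected [movie] (or a `widefield_result`, whose
#'   corrected ROI traces are then used directly).
#' @param target_freq Target frequency in Hz (< rate/2).
#' @param stim_window,baseline_window `c(start, end)` windows in seconds.
#' @param roi ROI edge length in pixels (default 2); ignored for
#'   `widefield_result` input.
#' @param segment_s Spectrogram segment length (s, default 0.5).
#' @param overlap Spectrogram overlap (default 0.75).
#' @return An object of class `power_map`: `map` (ROI-grid matrix of power
#'   differences), `target_freq`, the windows, and the actual frequency bin
#'   used.
#' @export
power_difference_map <- function(movie_corrected, target_freq,
                                 stim_window, baseline_window, roi = 2,
                                 segment_s = 0.5, overlap = 0.75) {
  if (inherits(movie_corrected, "widefield_result")) {
    M <- movie_corrected$corrected
    rate <- movie_corrected$rate
    roi_dim <- movie_corrected$roi_dim
  } else {
    stopifnot(inherits(movie_corrected, "movie"))
    M <- roi_matrix(movie_corrected, roi)
    rate <- movie_corrected$rate
    roi_dim <- attr(M, "roi_dim")
  }
  if (target_freq >= rate / 2) stop("target frequency above Nyquist")
  nper <- round(segment_s * rate)
  dur <- nrow(M) / rate
  for (w in list(stim_window, baseline_window)) {
    if (w[1] < 0 || w[2] > dur) stop("window outside the trial")
    if (w[2] - w[1] < segment_s) stop("window shorter than one spectrogram segment")
  }
  vals <- numeric(ncol(M))
  fbin <- NA_real_
  for (k in seq_len(ncol(M))) {
    sg <- spectrogram(trace(M[, k], rate), segment_s = segment_s, overlap = overlap)
    fi <- which.min(abs(sg$freq - target_freq))
    fbin <- sg$freq[fi]
    p <- sg$power[, fi]
    instim <- sg$time >= stim_window[1] & sg$time <= stim_window[2]
    inbase <- sg$time >= baseline_window[1] & sg$time <= baseline_window[2]
    if (!any(instim) || !any(inbase)) stop("window shorter than one spectrogram segment")
    vals[k] <- mean(p[instim]) - mean(p[inbase])
  }
  structure(list(map = matrix(vals, roi_dim[1], roi_dim[2]),
                 target_freq = target_freq, freq_bin = fbin,
                 stim_window = stim_window, baseline_window = baseline_window),
            class = "power_map")
}

#' @export
print.power_map <- function(x, ...) {
  cat(sprintf("<power_map> %dx%d ROIs at %g Hz (bin %g Hz), stim %g-%g s vs baseline %g-%g s\n",
              nrow(x$map), ncol(x$map), x$target_freq, x$freq_bin,
              x$stim_window[1], x$stim_window[2],
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Condition an LFP trace for comparison with imaging
#'
#' Applies the standard conditioning chain in order: polarity inversion
#' (optional), block-mean downsampling to the imaging rate, 70-Hz lowpass,
#' and an optional 60-Hz notch.
#'
#' @param lfp A [trace] (raw LFP).
#' @param target_rate Imaging rate in Hz (default 200).
#' @param invert Invert polarity first (default TRUE: depolarisation up).
#' @param lowpass Lowpass cutoff (Hz, default 70).
#' @param notch60 Apply a 60-Hz notch (default TRUE).
#' @return The conditioned [trace] at `target_rate`.
#' @export
condition_lfp <- function(lfp, target_rate = 200, invert = TRUE,
                          lowpass = 70, notch60 = TRUE) {
  stopifnot(inherits(lfp, "trace"))
  y <- lfp
  if (invert) y <- trace(-y$values, y$rate, y$t0_offset, y$units, y$polarity)
  if (y$rate != target_rate) y <- downsample(y, target_rate)
  if (!is.na(lowpass) && lowpass < y$rate / 2) y <- band_filter(y, c(NA, lowpass))
  if (notch60 && 62 < y$rate / 2) y <- notch_filter(y, 60, 4)
  y
}

#' Correlation map between imaging ROIs and a conditioned LFP
#'
#' Pearson correlation between the conditioned LFP and every corrected ROI
#' trace; invariant to affine rescaling of the LFP.
#'
#' @param result A `widefield_result` (or a plain n x n_roi matrix with
#'   attribute `roi_dim`).
#' @param lfp A conditioned [trace] at the imaging rate (see
#'   [condition_lfp()]), same length as the ROI traces.
#' @return An object of class `correlation_map`: `map` (ROI-grid matrix of
#'   r), `best_roi` (index of the maximal r).
#' @export
correlation_map <- function(result, lfp) {
  stopifnot(inherits(lfp, "trace"))
  if (inherits(result, "widefield_result")) {
    M <- result$corrected; roi_dim <- result$roi_dim; rate <- result$rate
  } else {
    M <- result; roi_dim <- attr(M, "roi_dim"); rate <- lfp$rate
  }
  if (lfp$rate != rate) stop("rate mismatch after conditioning")
  if (length(lfp$values) != nrow(M)) stop("length mismatch after conditioning")
  r <- as.vector(stats::cor(M, lfp$values))
  structure(list(map = matrix(r, roi_dim[1], roi_dim[2]),
                 best_roi = which.max(r)),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %dx%d ROIs, r in [%.3f, %.3f], best ROI %d\n",
              nrow(x$map), ncol(x$map), min(x$map), max(x$map), x$best_roi))
  invisible(x)
}

#' Modal best LFP channel across ROIs
#'
#' For multi-channel LFP recordings, finds per ROI the channel with the
#' maximal correlation, and returns the mode of that channel index across
#' ROIs (the channel that best matches the imaging signal overall).
#'
#' @param result A `widefield_result`.
#' @param lfp_channels List of conditioned [trace] objects, one per channel.
#' @param rois ROI indices to sample (default 8 evenly spaced ROIs).
#' @return List with `modal_channel` and `per_roi` (argmax channel per ROI).
#' @export
best_lfp_channel <- function(result, lfp_channels, rois = NULL) {
  stopifnot(inherits(result, "widefield_result"), length(lfp_channels) >= 1)
  nroi <- ncol(result$corrected)
  if (is.null(rois)) rois <- unique(round(seq(1, nroi, length.out = min(8, nroi))))
  per_roi <- vapply(rois, function(k) {
    rs <- vapply(lfp_channels, function(ch)
      stats::cor(result$corrected[, k], ch$values), numeric(1))
    which.max(rs)
  }, integer(1))
  tab <- table(per_roi)
  list(modal_channel = as.integer(names(tab)[which.max(tab)]), per_roi = per_roi)
}

#' Shuffled-control correlation distribution
#'
#' Generates surrogate imaging/LFP pairings by randomly mismatching trials
#' (derangements: no trial is ever paired with itself) and computes the
#' correlation for each mismatched pair, giving the null distribution against
#' which matched-trial correlations are compared.
#'
#' @param imaging_trials List of [trace] objects (one ROI trace per trial).
#' @param lfp_trials List of conditioned LFP [trace] objects, same length.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Integer seed; identical seeds give identical pairings.
#' @return Numeric vector of correlations, length `n_shuffles *
#'   length(trials)`.
#' @export
shuffled_control <- function(imaging_trials, lfp_trials, n_shuffles = 1000,
                             seed = 1L) {
  n <- length(imaging_trials)
  if (n < 2 || length(lfp_trials) != n) stop("need at least 2 matched trials")
  set.seed(seed)
  out <- numeric(0)
  for (s in seq_len(n_shuffles)) {
    repeat {                      # rejection-sample a derangement
      p <- sample.int(n)
      if (all(p != seq_len(n))) break
    }
    r <- vapply(seq_len(n), function(i)
      stats::cor(imaging_trials[[i]]$values, lfp_trials[[p[i]]]$values),
      numeric(1))
    out <- c(out, r)
  }
  out
}
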