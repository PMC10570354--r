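# High-throughput screening analytics: background/mask estimation, responsive
# pixel selection by SNR-maximising correlation-ranked batch accumulation,
# response amplitude, brightness, photostability and spectra processing.

#' Estimate background level and initial pixel mask from first frames
#'
#' Background is the location of the dominant low-intensity histogram mode
#' (256 bins over the lower half of the intensity range, robust to bright
#' foreground). The initial mask keeps pixels whose mean intensity exceeds
#' `background + k_sd * robust background sd` (MAD-based); pixels that reach
#' the saturation level in any of the frames are excluded.
#'
#' @param x A [movie]; its first `n_first` frames are used.
#' @param n_first Number of leading frames to use (default 10, capped at the
#'   frame count).
#' @param saturation_level Saturation threshold in counts; defaults to the
#'   movie's own.
#' @param k_sd Threshold multiplier over the robust background sd (default 5).
#' @return List with `background` (counts) and `mask` (a [pixel_mask]). An
#'   empty mask triggers a warning, not an error.
#' @export
estimate_background_and_mask <- function(x, n_first = 10,
                                         saturation_level = NULL, k_sd = 5) {
  stopifnot(inherits(x, "movie"))
  if (is.null(saturation_level)) saturation_level <- x$saturation_level
  nf <- min(n_first, n_frames(x))
  sub <- x$frames[seq_len(nf), , , drop = FALSE]
  mf <- apply(sub, c(2, 3), mean)
  saturated <- apply(sub >= saturation_level, c(2, 3), any)
  if (all(saturated)) stop("all pixels saturated")

  v <- mf[!saturated]
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    background <- lo
    bg_sd <- 0
  } else {
    half <- lo + (hi - lo) / 2
    vv <- v[v <= half]
    h <- graphics::hist(vv, breaks = seq(lo, half, length.out = 257), plot = FALSE)
    background <- h$mids[which.max(h$counts)]
    bg_sd <- stats::mad(vv, center = background)
  }
  thr <- background + k_sd * bg_sd
  mask <- mf > thr & !saturated
  if (!any(mask)) warning("initial mask is empty")
  list(background = background, mask = pixel_mask(mask))
}

# SNR of a detrended summed trace: peak |deviation| across protocol events
# over the sd of the event-free baseline
trace_snr <- function(tr, protocol, post_window = 0.5) {
  tt <- trace_times(tr)
  ev <- protocol$events
  in_event <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(ev)))
    in_event[tt >= ev$onset[i] & tt < ev$onset[i] + ev$duration[i] + post_window] <- TRUE
  if (all(in_event) || !any(in_event)) return(NA_real_)
  base <- tr$values[!in_event]
  mu <- mean(base); s <- stats::sd(base)
  peak <- max(abs(tr$values[in_event] - mu))
  if (s == 0) return(Inf)
  peak / s
}

#' Select responsive pixels by SNR-maximising batch accumulation
#'
#' Pixels in the initial mask are ranked by decreasing Pearson correlation of
#' their detrended trace with the overall (mask-summed) detrended trace, then
#' grouped in batches (default 200 pixels). Batches are accumulated from the
#' highest correlation down, and the returned secondary mask is the batch
#' prefix whose summed-trace SNR is maximal (ties broken toward fewer
#' batches). If fewer pixels than one batch are available the whole mask is
#' returned.
#'
#' @param movie_detr Detrended [movie] (e.g. from [detrend_divide()]).
#' @param initial A [pixel_mask]; must be non-empty.
#' @param protocol A [stimulus_protocol] with at least one event.
#' @param batch Batch size in pixels (default 200).
#' @return List with `mask` (secondary [pixel_mask], a subset of the initial
#'   mask), `snr` (of the selected mask's summed trace), and `prefix_snr`
#'   (the SNR of every batch prefix, for diagnostics).
#' @export
select_responsive_mask <- function(movie_detr, initial, protocol, batch = 200) {
  stopifnot(inherits(movie_detr, "movie"), nrow(protocol$events) >= 1)
  g <- mask_grid(initial)
  idx <- which(g)
  if (length(idx) == 0) stop("initial mask is empty")
  d <- dim(movie_detr$frames)
  flat <- matrix(movie_detr$frames, nrow = d[1])
  overall <- rowSums(flat[, idx, drop = FALSE])
  cors <- suppressWarnings(stats::cor(flat[, idx, drop = FALSE], overall))
  cors[is.na(cors)] <- -Inf
  ord <- idx[order(cors, decreasing = TRUE)]

  n_batches <- ceiling(length(ord) / batch)
  prefix_snr <- numeric(n_batches)
  for (b in seq_len(n_batches)) {
    sel <- ord[seq_len(min(b * batch, length(ord)))]
    tr <- trace(rowSums(flat[, sel, drop = FALSE]), movie_detr$rate)
    prefix_snr[b] <- trace_snr(tr, protocol)
  }
  best <- which.max(prefix_snr)           # which.max takes the first maximum:
  sel <- ord[seq_len(min(best * batch, length(ord)))]   # ties -> fewer batches
  m <- matrix(FALSE, d[2], d[3]); m[sel] <- TRUE
  tr <- trace(rowSums(flat[, sel, drop = FALSE]), movie_detr$rate)
  list(mask = pixel_mask(m), snr = trace_snr(tr, protocol),
       prefix_snr = prefix_snr)
}

#' Per-event response amplitude and width
#'
#' For each protocol event, the response amplitude is the peak fractional
#' deviation from the local pre-event baseline, signed by its actual
#' direction (this indicator family is negative-going, so screening responses
#' are typically negative). The response width is measured at a configurable
#' fraction of the peak (default 30%).
#'
#' @param x A detrended [trace] (values near 1 at baseline).
#' @param protocol A [stimulus_protocol]; events must fit inside the record.
#' @param baseline_s Length of the pre-event baseline window (s, default 0.2).
#' @param post_window Post-onset window searched for the peak, added to the
#'   event duration (s, default 0.3).
#' @param width_frac Fraction of the peak at which widths are measured
#'   (default 0.3).
#' @return Data frame with one row per event: `onset`, `amplitude` (signed
#'   dF/F fraction), `width_s` (`NA` when the response never falls back below
#'   the width level inside the window).
#' @export
response_amplitude <- function(x, protocol, baseline_s = 0.2,
                               post_window = 0.3, width_frac = 0.3) {
  stopifnot(inherits(x, "trace"))
  tt <- trace_times(x)
  ev <- protocol$events
  out <- data.frame(onset = ev$onset, amplitude = NA_real_, width_s = NA_real_)
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset[i]
    w_end <- on + ev$duration[i] + post_window
    if (w_end > max(tt) + 1 / x$rate)
      stop("event window truncated by record end (event ", i, ")")
    base_idx <- tt >= on - baseline_s & tt < on
    if (!any(base_idx)) stop("no baseline samples before event ", i)
    f0 <- mean(x$values[base_idx])
    win <- which(tt >= on & tt < w_end)
    dev <- x$values[win] / f0 - 1
    pk <- win[which.max(abs(dev))]
    amp <- x$values[pk] / f0 - 1
    out$amplitude[i] <- amp
    # width at width_frac of the peak
    level <- abs(amp) * width_frac
    above <- abs(x$values[win] / f0 - 1) >= level
    k <- which(win == pk)
    l <- k; while (l > 1 && above[l - 1]) l <- l - 1
    r <- k; while (r < length(win) && above[r + 1]) r <- r + 1
    if (l > 1 && r < length(win)) out$width_s[i] <- (r - l + 1) / x$rate
  }
  out
}

#' Green/red brightness ratio over a mask
#'
#' Ratio of mean background-subtracted green fluorescence to mean red
#' fluorescence over the selected pixels.
#'
#' @param green_frame,red_frame 2-D matrices (background-subtracted frames).
#' @param mask A [pixel_mask] or logical matrix; must be non-empty.
#' @return The dimensionless G/R ratio.
#' @export
brightness_ratio <- function(green_frame, red_frame, mask) {
  g <- mask_grid(mask)
  if (!any(g)) stop("mask is empty")
  mr <- mean(red_frame[g])
  if (mr <= 0) stop("red mean is not positive")
  mean(green_frame[g]) / mr
}

#' Combine per-FOV brightness ratios weighted by mask size
#'
#' Multi-field-of-view brightness: the mean G/R ratio across fields of view,
#' weighted by the number of pixels in each secondary mask.
#'
#' @param ratios Numeric vector of per-FOV ratios.
#' @param mask_sizes Pixel counts of the corresponding masks.
#' @return Weighted mean ratio.
#' @export
combine_brightness <- function(ratios, mask_sizes) {
  stopifnot(length(ratios) == length(mask_sizes), all(mask_sizes > 0))
  stats::weighted.mean(ratios, mask_sizes)
}

#' Photostability metrics: photon budget and half-life
#'
#' The photon budget is the area under the normalized fluorescence-vs-time
#' curve (trapezoidal, with the last sample held to the end of its frame so a
#' constant unit trace over `T` seconds yields exactly `T`). The half-life is
#' the first time at which a three-term exponential fit of the trace crosses
#' 0.5, or `NA` if it never does within the record.
#'
#' @param x A [trace] normalized to 1 at time 0.
#' @param tol Tolerance on the first sample being 1 (default 0.05).
#' @return List with `photon_budget` (s) and `half_life` (s or `NA`).
#' @export
photostability_metrics <- function(x, tol = 0.05) {
  stopifnot(inherits(x, "trace"))
  y <- x$values
  if (abs(y[1] - 1) > tol)
    stop("trace is not normalized: first value ", signif(y[1], 4), " differs from 1")
  dt <- 1 / x$rate
  n <- length(y)
  budget <- dt * (sum(y) - y[1] / 2 + y[n] / 2)
  trend <- fit_trend(x, n_terms = 3)
  dur <- trace_duration(x)
  grid <- seq(0, dur, length.out = 4096)
  tv <- eval_trend(trend, x$t0_offset + grid)
  below <- which(tv <= 0.5)
  half_life <- NA_real_
  if (length(below) > 0) {
    i <- below[1]
    if (i == 1) half_life <- grid[1]
    else half_life <- stats::uniroot(
      function(t) eval_trend(trend, x$t0_offset + t) - 0.5,
      c(grid[i - 1], grid[i]), tol = 1e-10)$root
  }
  list(photon_budget = budget, half_life = half_life)
}

#' Process excitation/emission spectral scans
#'
#' Each scan is corrected for autofluorescence by subtracting the mean blank
#' at every wavelength, normalized to its own peak, and excluded if its
#' normalized efficiency at the grid ends (350 or 535 nm for excitation
#' scans) exceeds the exclusion limit (default +-10%), which indicates
#' improper autofluorescence correction. Surviving normalized scans are
#' averaged and the average renormalized to peak 1; the peak wavelength is
#' the mean of the per-scan argmax wavelengths.
#'
#' @param wavelengths Shared wavelength grid (nm).
#' @param scans List of intensity vectors on that grid.
#' @param blanks List of blank (untransfected) scans on the same grid.
#' @param check_wavelengths Wavelengths at which the exclusion rule is applied
#'   (default `c(350, 535)`; only those present in the grid are checked).
#' @param exclusion_limit Normalized-efficiency limit (default 0.10).
#' @return List with `wavelength`, `spectrum` (peak-normalized average),
#'   `peak_wavelength` (nm), `n_used`, and `excluded` (indices of dropped
#'   scans).
#' @export
process_spectra <- function(wavelengths, scans, blanks,
                            check_wavelengths = c(350, 535),
                            exclusion_limit = 0.10) {
  stopifnot(length(scans) >= 1)
  for (s in c(scans, blanks)) if (length(s) != length(wavelengths))
    stop("scans and blanks must share the wavelength grid")
  blank <- if (length(blanks) > 0) Reduce(`+`, blanks) / length(blanks) else 0
  chk <- which(wavelengths %in% check_wavelengths)
  norm <- list(); peaks <- numeric(0); excluded <- integer(0)
  for (i in seq_along(scans)) {
    v <- scans[[i]] - blank
    pk <- max(v)
    if (pk <= 0) { excluded <- c(excluded, i); next }
    v <- v / pk
    if (length(chk) > 0 && any(abs(v[chk]) > exclusion_limit)) {
      excluded <- c(excluded, i); next
    }
    norm[[length(norm) + 1]] <- v
    peaks <- c(peaks, wavelengths[which.max(v)])
  }
  if (length(norm) == 0) stop("all scans excluded")
  avg <- Reduce(`+`, norm) / length(norm)
  avg <- avg / max(avg)
  list(wavelength = wavelengths, spectrum = avg,
       peak_wavelength = mean(peaks), n_used = length(norm),
       excluded = excluded)
}

#' Detect the excitation-light onset frame
#'
#' Returns the first frame whose mean intensity exceeds `threshold_frac`
#' times the steady-state (post-onset) mean; this frame serves as the time
#' reference for aligning stimulation events across fields of view. The
#' steady state is the median frame mean over the last half of the movie. On
#' a gradual ramp the earliest frame above threshold is returned; a movie that
#' is already bright at frame 0 returns index 0 with a warning.
#'
#' @param x A [movie] starting before the shutter opens.
#' @param threshold_frac Fraction of the steady-state mean (default 0.5).
#' @return 0-based frame index of light onset.
#' @export
detect_light_onset <- function(x, threshold_frac = 0.5) {
  stopifnot(inherits(x, "movie"))
  fm <- apply(x$frames, 1, mean)
  steady <- stats::median(fm[seq(ceiling(length(fm) / 2), length(fm))])
  above <- which(fm > threshold_frac * steady)
  if (length(above) == 0) stop("no light onset found")
  if (above[1] == 1) warning("movie is already bright at frame 0")
  above[1] - 1L
}

#' End-to-end screening metrics for one field of view
#'
#' Runs the screening chain: background and initial mask from the first
#' frames, three-term exponential trend fitted to the overall trace with
#' stimulation windows excluded, per-pixel divisive detrending, responsive
#' secondary-mask selection, per-event response amplitudes on the secondary
#' summed trace, and green/red brightness over the secondary mask.
#'
#' @param green A green-channel [movie].
#' @param red_frame A single-frame red [movie] (reference channel).
#' @param protocol A [stimulus_protocol].
#' @param batch Batch size for responsive-pixel selection.
#' @param exclude_pad Seconds appended to each event duration when excluding
#'   stimulation windows from the trend fit (default 0.3).
#' @return An object of class `screening_metrics`: `background_green`,
#'   `background_red`, `initial_mask`, `secondary_mask`, `snr`,
#'   `response_amplitudes` (per-event data frame), `brightness_gr`.
#' @export
screen_fov <- function(green, red_frame, protocol, batch = 200,
                       exclude_pad = 0.3) {
  est_g <- estimate_background_and_mask(green)
  est_r <- estimate_background_and_mask(red_frame, n_first = 1)
  d <- dim(green$frames)
  g_bs <- structure(list(frames = green$frames - est_g$background,
                         rate = green$rate, channel = "green",
                         saturation_level = green$saturation_level),
                    class = "movie")
  overall <- movie_trace(g_bs, est_g$mask)
  ex <- lapply(seq_len(nrow(protocol$events)), function(i)
    c(protocol$events$onset[i],
      protocol$events$onset[i] + protocol$events$duration[i] + exclude_pad))
  trend <- fit_trend(overall, exclude_windows = ex, n_terms = 3)
  g_detr <- detrend_divide(g_bs, trend, per_pixel = TRUE, mask = est_g$mask)
  sel <- select_responsive_mask(g_detr, est_g$mask, protocol, batch = batch)
  summed <- movie_trace(g_detr, sel$mask)
  amps <- response_amplitude(summed, protocol)
  gr <- brightness_ratio(
    apply(g_bs$frames[1:min(10, d[1]), , , drop = FALSE], c(2, 3), mean),
    red_frame$frames[1, , ] - est_r$background,
    sel$mask)
  structure(list(background_green = est_g$background,
                 background_red = est_r$background,
                 initial_mask = est_g$mask, secondary_mask = sel$mask,
                 snr = sel$snr, response_amplitudes = amps,
                 brightness_gr = gr),
            class = "screening_metrics")
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("<screening_metrics> bg %.4g, %d->%d pixels, SNR %.3g, G/R %.3g\n",
              x$background_green, mask_size(x$initial_mask),
              mask_size(x$secondary_mask), x$snr, x$brightness_gr))
  cat(sprintf("  response amplitudes: %s\n",
              paste(sprintf("%.3g", x$response_amplitudes$amplitude), collapse = ", ")))
  invisible(x)
}
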