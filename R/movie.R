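#' Time-major fluorescence movie
#'
#' Frames are stored time-major as a 3-D array `[frame, row, col]` so that
#' per-pixel trace extraction is contiguous. Frame `i` (0-based) is acquired at
#' time `i / rate` seconds.
#'
#' @param frames 3-D numeric array `[time, rows, cols]`, intensities >= 0.
#' @param rate Frame rate in Hz.
#' @param channel Channel label: `"green"` (indicator) or `"red"` (reference).
#' @param saturation_level Camera saturation level in counts (default 65535,
#'   16-bit class sCMOS/CMOS).
#' @return An object of class `movie`.
#' @export
movie <- function(frames, rate, channel = c("green", "red"),
                  saturation_level = 65535) {
  channel <- match.arg(channel)
  if (length(dim(frames)) != 3L) stop("shape not 3-D: frames must be [time, rows, cols]")
  if (!is.numeric(rate) || rate <= 0) stop("`rate` must be positive (Hz)")
  if (saturation_level <= 0) stop("`saturation_level` must be positive")
  if (dim(frames)[1] < 1L) stop("movie must contain at least one frame")
  if (min(frames) < 0) stop("intensities must be >= 0")
  structure(
    list(frames = frames, rate = rate, channel = channel,
         saturation_level = saturation_level),
    class = "movie"
  )
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie:%s> %d frames of %dx%d @ %g Hz (saturation %g)\n",
              x$channel, d[1], d[2], d[3], x$rate, x$saturation_level))
  invisible(x)
}

#' Number of frames in a movie
#' @param x A [movie].
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$frames)[1]

#' Summed or averaged trace over a pixel mask
#'
#' @param x A [movie].
#' @param mask A [pixel_mask] (or logical matrix) selecting pixels; `NULL`
#'   selects all pixels.
#' @param reduce `"sum"` or `"mean"` across selected pixels per frame.
#' @return A [trace] at the movie's frame rate.
#' @export
movie_trace <- function(x, mask = NULL, reduce = c("sum", "mean")) {
  reduce <- match.arg(reduce)
  stopifnot(inherits(x, "movie"))
  d <- dim(x$frames)
  flat <- matrix(x$frames, nrow = d[1])
  sel <- if (is.null(mask)) rep(TRUE, d[2] * d[3]) else as.vector(mask_grid(mask))
  if (!any(sel)) stop("mask selects no pixels")
  v <- if (reduce == "sum") rowSums(flat[, sel, drop = FALSE]) else
    rowMeans(flat[, sel, drop = FALSE])
  trace(v, x$rate, units = "counts")
}

#' Boolean pixel mask for a field of view
#'
#' @param grid Logical matrix (rows x cols) matching a movie's frame shape.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(grid) {
  if (!is.matrix(grid)) grid <- as.matrix(grid)
  storage.mode(grid) <- "logical"
  structure(list(grid = grid), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %dx%d, %d pixels selected\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Logical grid of a pixel mask
#' @param x A [pixel_mask] or logical matrix.
#' @return Logical matrix.
#' @export
mask_grid <- function(x) {
  if (inherits(x, "pixel_mask")) x$grid else {
    stopifnot(is.logical(x) || is.matrix(x)); x
  }
}

#' Count of selected pixels
#' @param x A [pixel_mask].
#' @return Integer.
#' @export
mask_size <- function(x) sum(mask_grid(x))

#' Paired green/red recording on a common clock
#'
#' The central object of the widefield pipeline: a green (indicator) movie and
#' a red (reference) movie sharing frame count, shape, and rate.
#'
#' @param green,red [movie] objects; must agree in frame count, shape, rate.
#' @param trial_id Label for the trial.
#' @param metadata Named list (mouse, session, stimulus, ...).
#' @return An object of class `dual_channel_recording`.
#' @export
dual_channel_recording <- function(green, red, trial_id = "trial-1",
                                   metadata = list()) {
  stopifnot(inherits(green, "movie"), inherits(red, "movie"))
  if (!identical(dim(green$frames), dim(red$frames)))
    stop("green and red channels must share frame count and shape")
  if (green$rate != red$rate) stop("green and red channels must share rate")
  structure(
    list(green = green, red = red, trial_id = trial_id, metadata = metadata),
    class = "dual_channel_recording"
  )
}

#' @export
print.dual_channel_recording <- function(x, ...) {
  d <- dim(x$green$frames)
  cat(sprintf("<dual_channel_recording '%s'> %d frames of %dx%d @ %g Hz\n",
              x$trial_id, d[1], d[2], d[3], x$green$rate))
  invisible(x)
}

#' Stimulus protocol: a list of timed events
#'
#' @param onset Numeric vector of event onsets (s), non-decreasing.
#' @param duration Event durations (s), positive; recycled.
#' @param kind Event kinds, one of `"efs_pulse"`, `"efs_train"`, `"step"`,
#'   `"ap_waveform"`, `"air_puff"`, `"flicker"`, `"whisker"`; recycled.
#' @param frequency Within-event frequency in Hz (`NA` for single pulses);
#'   recycled.
#' @param amplitude Event amplitude in protocol units; recycled.
#' @return An object of class `stimulus_protocol` wrapping a data frame of
#'   events.
#' @export
stimulus_protocol <- function(onset, duration, kind = "efs_pulse",
                              frequency = NA_real_, amplitude = 1) {
  kinds <- c("efs_pulse", "efs_train", "step", "ap_waveform", "air_puff",
             "flicker", "whisker")
  if (length(onset) == 0) stop("protocol needs at least one event")
  if (is.unsorted(onset)) stop("event onsets must be non-decreasing")
  ev <- data.frame(onset = onset, duration = duration, kind = kind,
                   frequency = frequency, amplitude = amplitude,
                   stringsAsFactors = FALSE)
  if (any(ev$duration <= 0)) stop("event durations must be positive")
  if (!all(ev$kind %in% kinds))
    stop("unknown event kind; must be one of: ", paste(kinds, collapse = ", "))
  structure(list(events = ev), class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %d events\n", nrow(x$events)))
  print(x$events)
  invisible(x)
}

#' The electric-field-stimulation screening protocol
#'
#' Four monophasic 1-ms square pulses at 2 Hz (500-ms period), then after a 1-s
#' gap a 100-Hz train of ten 2.5-ms pulses — the stimulation sequence used to
#' probe indicator responses in 96-well screening.
#'
#' @param t_start Onset of the first single pulse (s); stimulation begins 1 s
#'   after light onset in the screening acquisition, so the default is 1.
#' @return A [stimulus_protocol] with five events (4 single pulses + 1 train).
#' @export
efs_screen_protocol <- function(t_start = 1) {
  singles <- t_start + 0.5 * (0:3)
  train_onset <- singles[4] + 0.001 + 1   # 1-s gap after the last single pulse
  stimulus_protocol(
    onset = c(singles, train_onset),
    duration = c(rep(0.001, 4), 10 * 0.010),
    kind = c(rep("efs_pulse", 4), "efs_train"),
    frequency = c(rep(NA_real_, 4), 100),
    amplitude = c(rep(60, 4), 30)
  )
}

#' Run configuration for the widefield pipeline
#'
#' @param mode `"awake"`, `"anesthetized"`, or `"custom"`. Awake mode uses
#'   regression bands 10-30 / 1-10 / 0-1 Hz; anesthetized mode 4-20 / 1-4 /
#'   0-1 Hz (the heartbeat sits near 10-14 Hz awake and near 5 Hz under light
#'   anesthesia).
#' @param band_edges List of `c(low, high)` pairs in Hz, ordered high to low;
#'   `low = NA` means a pure lowpass. Defaults follow `mode`.
#' @param baseline_window Baseline window for F0 in seconds (default 2-2.5 s).
#' @param lowpass_cutoff Signal-channel lowpass cutoff in Hz (default 70).
#' @param seed Integer seed echoed into outputs.
#' @param roi_size ROI edge length in pixels (default 2, i.e. 2x2-pixel ROIs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("awake", "anesthetized", "custom"),
                       band_edges = NULL,
                       baseline_window = c(2.0, 2.5),
                       lowpass_cutoff = 70,
                       seed = 1L,
                       roi_size = 2L) {
  mode <- match.arg(mode)
  if (is.null(band_edges)) {
    band_edges <- switch(mode,
      awake = list(c(10, 30), c(1, 10), c(NA, 1)),
      anesthetized = list(c(4, 20), c(1, 4), c(NA, 1)),
      custom = stop("custom mode requires explicit `band_edges`"))
  }
  highs <- vapply(band_edges, function(b) b[2], numeric(1))
  if (is.unsorted(rev(highs), strictly = TRUE))
    stop("bands must be ordered high to low frequency")
  for (b in band_edges) {
    if (!is.na(b[1]) && b[1] >= b[2]) stop("band low edge must be below high edge")
  }
  if (baseline_window[1] >= baseline_window[2])
    stop("baseline window must have positive length")
  structure(
    list(mode = mode, band_edges = band_edges,
         baseline_window = baseline_window, lowpass_cutoff = lowpass_cutoff,
         seed = as.integer(seed), roi_size = as.integer(roi_size)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  bands <- vapply(x$band_edges, function(b)
    sprintf("%s-%g", ifelse(is.na(b[1]), "0", format(b[1])), b[2]), character(1))
  cat(sprintf("<run_config> mode=%s bands=[%s] Hz baseline=%g-%g s lowpass=%g Hz roi=%dx%d\n",
              x$mode, paste(bands, collapse = ", "),
              x$baseline_window[1], x$baseline_window[2],
              x$lowpass_cutoff, x$roi_size, x$roi_size))
  invisible(x)
}
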