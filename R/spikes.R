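# Spike detection in command-voltage and fluorescence traces, and
# precision/recall/F1 scoring with time-bin matching.

# local maxima with topographic prominence (the height a peak stands above
# the higher of the two minima separating it from taller terrain)
find_peaks <- function(y, min_prominence = 0, min_distance_samples = 1) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    lo <- i; left_min <- y[i]
    while (lo > 1 && y[lo - 1] <= y[i]) { lo <- lo - 1; left_min <- min(left_min, y[lo]) }
    left_base <- if (lo == 1 && y[lo] <= y[i]) min(y[1:i]) else left_min
    hi <- i; right_min <- y[i]
    while (hi < n && y[hi + 1] <= y[i]) { hi <- hi + 1; right_min <- min(right_min, y[hi]) }
    right_base <- if (hi == n && y[hi] <= y[i]) min(y[i:n]) else right_min
    y[i] - max(left_base, right_base)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) == 0) return(integer(0))
  # enforce minimum distance, keeping higher peaks first
  ord <- keep[order(y[keep], decreasing = TRUE)]
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(i - taken) >= min_distance_samples)) taken <- c(taken, i)
  }
  sort(taken)
}

#' Detect spikes in a command-voltage trace
#'
#' Local maxima with a minimum peak prominence of 10 (mV) and a minimum peak
#' separation of 1 ms, defining the ground-truth spike times of a
#' voltage-clamp waveform.
#'
#' @param x A [trace] in mV.
#' @param prominence Minimum peak prominence (default 10 mV).
#' @param min_distance Minimum peak separation in seconds (default 0.001).
#' @return Numeric vector of spike times (s) at the peak samples.
#' @export
detect_command_spikes <- function(x, prominence = 10, min_distance = 0.001) {
  stopifnot(inherits(x, "trace"))
  if (length(x$values) == 0) stop("empty trace")
  idx <- find_peaks(x$values, min_prominence = prominence,
                    min_distance_samples = max(1L, round(min_distance * x$rate)))
  trace_times(x)[idx]
}

#' Detect spikes in a fluorescence trace by simple thresholding
#'
#' The trace is rectified according to its polarity (negative-going indicators
#' are negated), high-pass filtered (default 60 Hz, removing slow components
#' such as baseline rise during current injection), and peaks with amplitude
#' larger than `threshold_mult` times the noise level are returned. The noise
#' level sigma is the standard deviation of the filtered trace over a
#' spike-free baseline window (default the first 500 ms).
#'
#' @param x A [trace] with declared polarity.
#' @param baseline_window Spike-free baseline `c(start, end)` in seconds, or a
#'   single number meaning the first that many seconds (default 0.5).
#' @param threshold_mult Threshold in units of sigma (default 2).
#' @param highpass High-pass cutoff in Hz (default 60); `NA` skips filtering.
#' @param min_distance Minimum peak separation (s, default 0.001).
#' @return Numeric vector of detected spike times (s).
#' @export
detect_fluor_spikes <- function(x, baseline_window = 0.5, threshold_mult = 2,
                                highpass = 60, min_distance = 0.001) {
  stopifnot(inherits(x, "trace"))
  if (length(baseline_window) == 1) baseline_window <- c(0, baseline_window) + x$t0_offset
  if (baseline_window[2] - baseline_window[1] > trace_duration(x))
    stop("baseline window exceeds record")
  y <- if (x$polarity == "negative_up") -x$values else x$values
  if (!is.na(highpass)) y <- butter_filtfilt(y, x$rate, "high", highpass, order = 4)
  tt <- trace_times(x)
  base <- y[tt >= baseline_window[1] & tt < baseline_window[2]]
  if (length(base) < 2) stop("baseline window selects too few samples")
  sigma <- stats::sd(base)
  thr <- threshold_mult * sigma
  idx <- find_peaks(y, min_prominence = 0,
                    min_distance_samples = max(1L, round(min_distance * x$rate)))
  # amplitudes are measured relative to the baseline level
  idx <- idx[y[idx] - mean(base) > thr]
  tt[idx]
}

#' Match detected spikes against ground truth and score precision/recall/F1
#'
#' Looping over the ground-truth spikes from first to last, each truth spike
#' is matched to the nearest unmatched detection within `+- time_bin` (ties
#' broken toward the earlier detection) and the pair is removed. Then
#' `TP` = matched pairs, `FP` = detections left unmatched, `FN` = truth spikes
#' left unmatched, `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, and
#' `F1 = 2PR/(P+R)`. The automatic time bin is the minimum distance between
#' neighbouring truth spikes. Degenerate conventions: an empty side gives
#' precision/recall 0 and F1 0, except that empty truth AND empty detections
#' score F1 = 1 (perfect silence).
#'
#' @param truth_times Ground-truth spike times (s).
#' @param detected_times Detected spike times (s).
#' @param time_bin Matching half-window (s), or `"auto"` (needs >= 2 truth
#'   spikes).
#' @return An object of class `spike_match_result` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `time_bin`, and `matched_pairs` (data frame
#'   of truth/detected times).
#' @export
match_and_score <- function(truth_times, detected_times, time_bin = "auto") {
  truth <- sort(as.numeric(truth_times))
  det <- sort(as.numeric(detected_times))
  if (identical(time_bin, "auto")) {
    if (length(truth) < 2)
      stop("automatic time bin requires at least 2 ground-truth spikes")
    time_bin <- min(diff(truth))
  }
  matched <- logical(length(det))
  pairs_t <- numeric(0); pairs_d <- numeric(0)
  for (ts in truth) {
    if (length(det) == 0) break
    free <- which(!matched)
    if (length(free) == 0) break
    dt <- abs(det[free] - ts)
    ok <- free[dt <= time_bin]
    if (length(ok) == 0) next
    dts <- abs(det[ok] - ts)
    # nearest; tie -> earlier detection (ok is sorted by time, which.min
    # returns the first minimum)
    j <- ok[which.min(dts)]
    matched[j] <- TRUE
    pairs_t <- c(pairs_t, ts); pairs_d <- c(pairs_d, det[j])
  }
  tp <- length(pairs_t)
  fp <- length(det) - tp
  fn <- length(truth) - tp
  if (length(truth) == 0 && length(det) == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  }
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 time_bin = time_bin,
                 matched_pairs = data.frame(truth_time = pairs_t,
                                            detected_time = pairs_d)),
            class = "spike_match_result")
}

#' @export
print.spike_match_result <- function(x, ...) {
  cat(sprintf("<spike_match_result> TP %d, FP %d, FN %d | P %.3f R %.3f F1 %.3f (bin %.4g s)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$time_bin))
  invisible(x)
}

#' Restrict spike times to a scoring window
#'
#' Scoring of high-frequency firing episodes is restricted to the spikes
#' inside the stimulation period (e.g. 0.25-0.75 s after waveform onset);
#' the window is half-open `[from, to)`.
#'
#' @param times Spike times (s).
#' @param from,to Window bounds (s).
#' @return Times within the window.
#' @export
spikes_in_window <- function(times, from = 0.25, to = 0.75) {
  times[times >= from & times < to]
}
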