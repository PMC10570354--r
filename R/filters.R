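# Zero-phase Butterworth filtering shared by the spike, widefield and spectral
# modules. All filters are 4th-order Butterworth applied forward-backward
# (signal::filtfilt), so the effective response is 8th-order with zero phase
# and band edges at half-power.

butter_filtfilt <- function(x, rate, type, cutoff, order = 4) {
  nyq <- rate / 2
  if (any(cutoff >= nyq)) stop("Nyquist violation: cutoff ", paste(cutoff, collapse = "-"),
                               " Hz >= ", nyq, " Hz")
  if (any(cutoff <= 0)) stop("cutoff must be positive")
  bf <- signal::butter(order, cutoff / nyq, type = type)
  # reflect-pad to suppress filtfilt edge transients
  n <- length(x)
  npad <- min(n - 1, max(order * 25, ceiling(3 * rate / min(cutoff))))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x, 2 * x[n] - rev(x[(n - npad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + n)]
}

#' Zero-phase band-limited filtering of a trace
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero phase,
#' half-power band edges). `band = c(NA, high)` gives a lowpass, `c(low, NA)` a
#' highpass, and `c(low, high)` a bandpass.
#'
#' @param x A [trace].
#' @param band Two-element numeric `c(low, high)` in Hz; `NA` opens that side.
#' @param order Filter order per pass (default 4).
#' @return The filtered [trace].
#' @export
band_filter <- function(x, band, order = 4) {
  stopifnot(inherits(x, "trace"), length(band) == 2)
  lo <- band[1]; hi <- band[2]
  y <- if (is.na(lo) && is.na(hi)) {
    stop("band must constrain at least one edge")
  } else if (is.na(lo)) {
    butter_filtfilt(x$values, x$rate, "low", hi, order)
  } else if (is.na(hi)) {
    butter_filtfilt(x$values, x$rate, "high", lo, order)
  } else {
    if (lo >= hi) stop("band low edge must be below high edge")
    butter_filtfilt(x$values, x$rate, "pass", c(lo, hi), order)
  }
  trace(y, x$rate, t0_offset = x$t0_offset, units = x$units, polarity = x$polarity)
}

#' Zero-phase notch (band-stop) filter
#'
#' @param x A [trace].
#' @param center Center frequency in Hz (default 60, mains hum).
#' @param width Full stop-band width in Hz (default 4).
#' @param order Filter order per pass.
#' @return The filtered [trace].
#' @export
notch_filter <- function(x, center = 60, width = 4, order = 4) {
  stopifnot(inherits(x, "trace"))
  y <- butter_filtfilt(x$values, x$rate, "stop",
                       c(center - width / 2, center + width / 2), order)
  trace(y, x$rate, t0_offset = x$t0_offset, units = x$units, polarity = x$polarity)
}
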