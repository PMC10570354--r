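# Welch-averaged (cross-)spectra on top of stats::fft: power spectral density,
# spectrogram, and magnitude-squared coherence. One-sided density scaling, Hann
# window, per-segment mean removal, so sum(psd) * df approximates the signal
# variance (Parseval).

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)

# Averaged auto/cross spectral densities over overlapping windowed segments.
# Returns complex Pxy when y is given, real Pxx otherwise.
segment_spectra <- function(x, y = NULL, fs, nperseg, overlap) {
  n <- length(x)
  if (nperseg > n) stop("record shorter than one segment")
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- floor(nperseg / 2) + 1L
  acc <- if (is.null(y)) numeric(nfreq) else complex(nfreq)
  for (s in starts) {
    xs <- x[s:(s + nperseg - 1L)]
    Xf <- stats::fft(w * (xs - mean(xs)))[1:nfreq]
    if (is.null(y)) {
      acc <- acc + Re(Xf * Conj(Xf))
    } else {
      ys <- y[s:(s + nperseg - 1L)]
      Yf <- stats::fft(w * (ys - mean(ys)))[1:nfreq]
      acc <- acc + Xf * Conj(Yf)
    }
  }
  p <- acc / length(starts) * scale
  # one-sided: double everything except DC (and Nyquist when nperseg is even)
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  list(freq = (0:(nfreq - 1)) * fs / nperseg,
       p = p * dbl,
       n_segments = length(starts))
}

#' Welch power spectral density
#'
#' One-sided Welch estimate with Hann window and per-segment mean removal.
#' `sum(power) * df` approximates the trace variance.
#'
#' @param x A [trace].
#' @param nperseg Segment length in samples (default: `length/4` capped at
#'   1024, floor 16).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `freq` (Hz), `power` (units^2/Hz), `df` (Hz), and
#'   `n_segments`.
#' @export
welch_psd <- function(x, nperseg = NULL, overlap = 0.5) {
  stopifnot(inherits(x, "trace"))
  n <- length(x$values)
  if (is.null(nperseg)) nperseg <- max(16L, min(1024L, floor(n / 4)))
  if (n < 2 * nperseg * (1 - overlap) + nperseg)
    if (n < nperseg) stop("trace too short for Welch estimate")
  sp <- segment_spectra(x$values, fs = x$rate, nperseg = nperseg, overlap = overlap)
  list(freq = sp$freq, power = Re(sp$p), df = x$rate / nperseg,
       n_segments = sp$n_segments)
}

#' Frequency of the dominant spectral peak
#'
#' @param psd A list from [welch_psd()].
#' @param above Only consider frequencies strictly above this value (Hz);
#'   default 0 excludes only DC.
#' @return Peak frequency in Hz.
#' @export
psd_peak_freq <- function(psd, above = 0) {
  keep <- psd$freq > above
  if (!any(keep)) stop("no frequencies above ", above, " Hz")
  psd$freq[keep][which.max(psd$power[keep])]
}

#' Short-time power spectrogram
#'
#' Hann-windowed short-time FFT power with density scaling, used for
#' stimulation-frequency power maps.
#'
#' @param x A [trace].
#' @param segment_s Segment length in seconds (default 0.5).
#' @param overlap Fractional overlap (default 0.75).
#' @return List with `freq` (Hz), `time` (segment centers, s), and `power`
#'   (matrix, time x frequency).
#' @export
spectrogram <- function(x, segment_s = 0.5, overlap = 0.75) {
  stopifnot(inherits(x, "trace"))
  nperseg <- round(segment_s * x$rate)
  n <- length(x$values)
  if (nperseg > n) stop("window shorter than one spectrogram segment")
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- 1 / (x$rate * sum(w^2))
  nfreq <- floor(nperseg / 2) + 1L
  dbl <- rep(2, nfreq); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nfreq] <- 1
  pw <- matrix(NA_real_, nrow = length(starts), ncol = nfreq)
  for (i in seq_along(starts)) {
    xs <- x$values[starts[i]:(starts[i] + nperseg - 1L)]
    Xf <- stats::fft(w * (xs - mean(xs)))[1:nfreq]
    pw[i, ] <- Re(Xf * Conj(Xf)) * scale * dbl
  }
  list(freq = (0:(nfreq - 1)) * x$rate / nperseg,
       time = x$t0_offset + (starts - 1 + nperseg / 2) / x$rate,
       power = pw)
}

#' Magnitude-squared coherence between two traces
#'
#' Welch-based estimate `|Pxy|^2 / (Pxx * Pyy)`, bounded in `[0, 1]`,
#' quantifying frequency-resolved similarity of two signals (e.g. a corrected
#' imaging ROI trace and an LFP channel).
#'
#' @param a,b [trace] objects with equal rates and lengths.
#' @param segment_s Segment length in seconds (default 2).
#' @param overlap Fractional overlap (default 0.5).
#' @return An object of class `coherence_result`: `freq` (Hz), `msc` in
#'   `[0,1]`, and segment parameters.
#' @export
coherence <- function(a, b, segment_s = 2.0, overlap = 0.5) {
  stopifnot(inherits(a, "trace"), inherits(b, "trace"))
  if (a$rate != b$rate) stop("traces must share a rate")
  if (length(a$values) != length(b$values)) stop("traces must share a length")
  nperseg <- round(segment_s * a$rate)
  n <- length(a$values)
  step <- max(1L, floor(nperseg * (1 - overlap)))
  nseg <- if (n >= nperseg) length(seq(1L, n - nperseg + 1L, by = step)) else 0
  if (nseg < 2) stop("record shorter than 2 segments; reduce segment_s")
  pxx <- segment_spectra(a$values, fs = a$rate, nperseg = nperseg, overlap = overlap)
  pyy <- segment_spectra(b$values, fs = b$rate, nperseg = nperseg, overlap = overlap)
  pxy <- segment_spectra(a$values, b$values, fs = a$rate, nperseg = nperseg,
                         overlap = overlap)
  msc <- Mod(pxy$p)^2 / (Re(pxx$p) * Re(pyy$p))
  msc[!is.finite(msc)] <- 0
  msc <- pmin(1, pmax(0, msc))
  structure(list(freq = pxx$freq, msc = msc, segment_s = segment_s,
                 overlap = overlap, n_segments = pxx$n_segments),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d frequencies up to %g Hz, %d segments of %g s\n",
              length(x$freq), max(x$freq), x$n_segments, x$segment_s))
  invisible(x)
}
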