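#' Uniformly sampled scalar time series
#'
#' A `trace` holds a uniformly sampled fluorescence, voltage, or LFP signal
#' together with its sampling rate and time origin. Sample `i` (0-based) sits at
#' time `t0_offset + i / rate` seconds.
#'
#' @param values Numeric vector of sample values (arbitrary units).
#' @param rate Sampling rate in Hz; must be positive.
#' @param t0_offset Time of sample 0 in seconds.
#' @param units Label for the value axis (e.g. `"dF/F"`, `"mV"`, `"counts"`).
#' @param polarity Signal polarity: `"positive_up"` (default) or
#'   `"negative_up"` for indicators whose transients deflect downward.
#' @return An object of class `trace`.
#' @examples
#' tr <- trace(sin(2 * pi * 5 * seq(0, 1, by = 1 / 200)), rate = 200)
#' trace_times(tr)[1:3]
#' @export
trace <- function(values, rate, t0_offset = 0, units = "au",
                  polarity = c("positive_up", "negative_up")) {
  polarity <- match.arg(polarity)
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (anyNA(values) || any(!is.finite(values)))
    stop("`values` must be finite; flag missing data explicitly before building a trace")
  structure(
    list(values = values, rate = rate, t0_offset = t0_offset,
         units = units, polarity = polarity),
    class = "trace"
  )
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %d samples @ %g Hz, t0 = %g s, units = %s, polarity = %s\n",
              length(x$values), x$rate, x$t0_offset, x$units, x$polarity))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param x A [trace].
#' @return Numeric vector of times (s), one per sample.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0_offset + (seq_along(x$values) - 1) / x$rate
}

#' Duration of a trace in seconds
#' @param x A [trace].
#' @return Length of the record in seconds (`n / rate`).
#' @export
trace_duration <- function(x) length(x$values) / x$rate

#' Convert a time (s) to the nearest 0-based sample index
#' @param x A [trace].
#' @param t Time(s) in seconds.
#' @return Integer 0-based index; exact for times on the sample grid.
#' @export
time_to_index <- function(x, t) {
  stopifnot(inherits(x, "trace"))
  as.integer(round((t - x$t0_offset) * x$rate))
}

#' Crop a trace to a time window
#' @param x A [trace].
#' @param from,to Window bounds in seconds (half-open `[from, to)` on the
#'   sample grid; `to` may be `Inf`).
#' @return A [trace] covering the window, with `t0_offset` updated.
#' @export
trace_window <- function(x, from, to = Inf) {
  stopifnot(inherits(x, "trace"))
  tt <- trace_times(x)
  keep <- tt >= from & tt < to
  if (!any(keep)) stop("window [", from, ", ", to, ") selects no samples")
  i0 <- which(keep)[1]
  trace(x$values[keep], x$rate, t0_offset = tt[i0], units = x$units,
        polarity = x$polarity)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$values)
}
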