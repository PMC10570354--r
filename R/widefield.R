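# In vivo widefield preprocessing: background subtraction, bleach-template
# detrending of the indicator channel, dF/F0, a 70-Hz lowpass, and sequential
# band-filtered reference regression (heartbeat and slow hemodynamics are
# shared between the indicator and reference channels; voltage is not).

#' Subtract per-channel background from a dual-channel recording
#'
#' @param rec A [dual_channel_recording].
#' @param bg_green,bg_red Scalar background level or a per-pixel matrix
#'   matching the frame shape (e.g. the mean of a control movie).
#' @return The recording with both channels reduced. Negative values are kept
#'   (floating point); a warning is raised when more than 1% of pixels go
#'   negative.
#' @export
subtract_background <- function(rec, bg_green, bg_red) {
  stopifnot(inherits(rec, "dual_channel_recording"))
  sub1 <- function(mov, bg) {
    d <- dim(mov$frames)
    if (is.matrix(bg)) {
      if (!identical(dim(bg), d[2:3])) stop("background map shape mismatch")
      fr <- sweep(matrix(mov$frames, nrow = d[1]), 2, as.vector(bg))
      fr <- array(fr, d)
    } else {
      fr <- mov$frames - bg
    }
    frac_neg <- mean(fr < 0)
    if (frac_neg > 0.01)
      warning(sprintf("%.1f%% of %s-channel pixels negative after background subtraction",
                      100 * frac_neg, mov$channel))
    structure(list(frames = fr, rate = mov$rate, channel = mov$channel,
                   saturation_level = mov$saturation_level), class = "movie")
  }
  dual_channel_recording(sub1(rec$green, bg_green), sub1(rec$red, bg_red),
                         trial_id = rec$trial_id, metadata = rec$metadata)
}

#' Estimate a two-term exponential bleach template from traces
#'
#' Each trace is lowpass filtered at 0.5 Hz, the filtered traces are averaged,
#' and the average is fitted to a two-term exponential model (plus offset).
#' The template captures the fast photobleaching common to a session and is
#' removed from single trials by division (or subtraction).
#'
#' @param traces List of [trace] objects with uniform length and rate; each
#'   must be at least 2 s long.
#' @param lowpass_cutoff Lowpass cutoff in Hz (default 0.5).
#' @return An object of class `bleach_template` (an `exp_trend` plus
#'   `n_traces_used` and `lowpass_cutoff`).
#' @export
estimate_bleach_template <- function(traces, lowpass_cutoff = 0.5) {
  stopifnot(length(traces) >= 1)
  r <- traces[[1]]$rate; n <- length(traces[[1]]$values)
  for (tr in traces) {
    stopifnot(inherits(tr, "trace"))
    if (tr$rate != r || length(tr$values) != n)
      stop("traces must share length and rate")
    if (trace_duration(tr) < 2) stop("traces shorter than 2 s")
  }
  filt <- vapply(traces, function(tr)
    butter_filtfilt(tr$values, r, "low", lowpass_cutoff, order = 4), numeric(n))
  avg <- trace(rowMeans(as.matrix(filt)), r, t0_offset = traces[[1]]$t0_offset)
  trend <- fit_trend(avg, n_terms = 2)
  trend$n_traces_used <- length(traces)
  trend$lowpass_cutoff <- lowpass_cutoff
  class(trend) <- c("bleach_template", "exp_trend")
  trend
}

#' Fractional fluorescence change relative to a baseline window
#'
#' `dF/F0 = (F - F0) / F0` with `F0` the mean fluorescence over the baseline
#' window (default 2-2.5 s into the trial).
#'
#' @param x A [trace]; `F0` must be positive.
#' @param baseline_window `c(start, end)` seconds; must lie inside the record.
#' @return A dimensionless [trace]; exactly zero over the baseline window for
#'   constant input.
#' @export
compute_dff <- function(x, baseline_window = c(2.0, 2.5)) {
  stopifnot(inherits(x, "trace"))
  tt <- trace_times(x)
  sel <- tt >= baseline_window[1] & tt < baseline_window[2]
  if (!any(sel)) stop("baseline window lies outside the record")
  f0 <- mean(x$values[sel])
  if (f0 <= 0) stop("baseline F0 is not positive")
  trace(x$values / f0 - 1, x$rate, t0_offset = x$t0_offset, units = "dF/F",
        polarity = x$polarity)
}

#' One ordinary-least-squares reference-regression step
#'
#' Finds the scale `beta` minimising `||g - beta * r (- alpha)||^2` and
#' returns `g - beta * r (- alpha)`: the component of the signal explained by
#' the band-filtered reference is removed, leaving the residual orthogonal to
#' the regressor. Regression is scale-only by default ("scaled and
#' subtracted"); an intercept can be added for the DC band.
#'
#' @param signal_dff Signal-channel dF/F [trace] (`g_n`).
#' @param ref_band Band-filtered reference dF/F [trace] (`r_n`); equal length
#'   and rate, non-zero variance.
#' @param with_intercept Include an intercept alpha (default FALSE).
#' @param band Optional `c(low, high)` recorded in the step for bookkeeping.
#' @return List with `trace` (the corrected `g_{n+1}`) and `step`, a
#'   `regression_step` (`band`, `beta`, `intercept`).
#' @export
regress_step <- function(signal_dff, ref_band, with_intercept = FALSE,
                         band = c(NA_real_, NA_real_)) {
  stopifnot(inherits(signal_dff, "trace"), inherits(ref_band, "trace"))
  g <- signal_dff$values; r <- ref_band$values
  if (length(g) != length(r) || signal_dff$rate != ref_band$rate)
    stop("signal and reference must share length and rate")
  if (stats::var(r) == 0) stop("reference band has zero variance")
  if (with_intercept) {
    fit <- stats::.lm.fit(cbind(1, r), g)
    alpha <- fit$coefficients[1]; beta <- fit$coefficients[2]
    out <- g - beta * r - alpha
  } else {
    beta <- sum(g * r) / sum(r * r)
    alpha <- 0
    out <- g - beta * r
  }
  list(trace = trace(out, signal_dff$rate, t0_offset = signal_dff$t0_offset,
                     units = signal_dff$units, polarity = signal_dff$polarity),
       step = structure(list(band = band, beta = beta, intercept = alpha,
                             with_intercept = with_intercept),
                        class = "regression_step"))
}

#' @export
print.regression_step <- function(x, ...) {
  b <- if (all(is.na(x$band))) "full-band" else
    sprintf("%s-%g Hz", ifelse(is.na(x$band[1]), "0", format(x$band[1])), x$band[2])
  cat(sprintf("<regression_step> %s: beta = %.4g%s\n", b, x$beta,
              if (x$with_intercept) sprintf(", intercept = %.4g", x$intercept) else ""))
  invisible(x)
}

# mean traces over roi_size x roi_size blocks; returns n x n_roi matrix
roi_matrix <- function(mov, roi_size) {
  d <- dim(mov$frames)
  nr <- d[2] %/% roi_size; nc <- d[3] %/% roi_size
  if (nr < 1 || nc < 1) stop("roi_size larger than the frame")
  flat <- matrix(mov$frames, nrow = d[1])
  out <- matrix(0, d[1], nr * nc)
  k <- 0
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    rows <- ((i - 1) * roi_size + 1):(i * roi_size)
    cols <- ((j - 1) * roi_size + 1):(j * roi_size)
    pix <- as.vector(outer(rows, (cols - 1) * d[2], `+`))
    k <- k + 1
    out[, k] <- rowMeans(flat[, pix, drop = FALSE])
  }
  attr(out, "roi_dim") <- c(nr, nc)
  out
}

#' Run the dual-channel artifact-removal pipeline
#'
#' Ordered stages: per-channel background subtraction; divisive (or
#' subtractive) bleach-template detrending of the green channel; dF/F0 on
#' both channels; 70-Hz lowpass on the green channel; then one OLS regression
#' step per configured frequency band, high to low, each removing the
#' component of the signal explained by the band-filtered reference. Run per
#' ROI (default 2x2 pixels; `roi_size = 1` gives the pixel-wise path).
#'
#' @param rec A [dual_channel_recording].
#' @param cfg A [run_config]; its bands, baseline window, lowpass cutoff and
#'   ROI size drive the stages.
#' @param bg_green,bg_red Background levels (scalar or per-pixel matrix).
#' @param bleach_template Optional `bleach_template`; when `NULL`, estimated
#'   from the ROI traces of this recording via [estimate_bleach_template()].
#' @param detrend `"divide"` (default) or `"subtract"` for bleach removal.
#' @param intercept_dc_band Add an intercept in the lowest (DC) band's
#'   regression step (default FALSE).
#' @return An object of class `widefield_result`: `corrected` (n x n_roi
#'   matrix of corrected green dF/F), `uncorrected` (green dF/F before
#'   regression), `ref_dff`, `steps` (per band, vector of betas across ROIs),
#'   `roi_dim`, `rate`, `cfg`.
#' @export
run_pipeline <- function(rec, cfg = run_config("anesthetized"),
                         bg_green = 0, bg_red = 0, bleach_template = NULL,
                         detrend = c("divide", "subtract"),
                         intercept_dc_band = FALSE) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(rec, "dual_channel_recording"), inherits(cfg, "run_config"))
  rate <- rec$green$rate
  rec <- subtract_background(rec, bg_green, bg_red)
  G <- roi_matrix(rec$green, cfg$roi_size)
  R <- roi_matrix(rec$red, cfg$roi_size)
  roi_dim <- attr(G, "roi_dim")
  n <- nrow(G); nroi <- ncol(G)
  tt <- (0:(n - 1)) / rate

  if (is.null(bleach_template)) {
    trs <- lapply(seq_len(nroi), function(k) trace(G[, k], rate))
    bleach_template <- estimate_bleach_template(trs)
  }
  tv <- eval_trend(bleach_template, tt)
  if (detrend == "divide") {
    if (any(tv <= 0)) stop("stage bleach-detrend: template not positive over trial")
    # normalise so division rescales, not re-levels, each ROI
    G <- G / (tv / mean(tv))
  } else {
    G <- G - (tv - mean(tv))
  }

  dff <- function(M) {
    sel <- tt >= cfg$baseline_window[1] & tt < cfg$baseline_window[2]
    if (!any(sel)) stop("stage dF/F: baseline window outside the trial")
    f0 <- colMeans(M[sel, , drop = FALSE])
    if (any(f0 <= 0)) stop("stage dF/F: non-positive baseline F0")
    sweep(sweep(M, 2, f0, `/`), 2, 1)
  }
  G1 <- dff(G)
  R1 <- dff(R)
  if (cfg$lowpass_cutoff < rate / 2) {
    for (k in seq_len(nroi))
      G1[, k] <- butter_filtfilt(G1[, k], rate, "low", cfg$lowpass_cutoff, order = 4)
  }
  uncorrected <- G1

  betas <- matrix(NA_real_, length(cfg$band_edges), nroi)
  is_dc <- vapply(cfg$band_edges, function(b) is.na(b[1]), logical(1))
  for (bi in seq_along(cfg$band_edges)) {
    b <- cfg$band_edges[[bi]]
    for (k in seq_len(nroi)) {
      rb <- if (is.na(b[1]))
        butter_filtfilt(R1[, k], rate, "low", b[2], order = 4)
      else
        butter_filtfilt(R1[, k], rate, "pass", b, order = 4)
      st <- regress_step(trace(G1[, k], rate), trace(rb, rate),
                         with_intercept = intercept_dc_band && is_dc[bi],
                         band = b)
      G1[, k] <- st$trace$values
      betas[bi, k] <- st$step$beta
    }
  }
  structure(list(corrected = G1, uncorrected = uncorrected, ref_dff = R1,
                 steps = betas, roi_dim = roi_dim, rate = rate, cfg = cfg,
                 bleach_template = bleach_template),
            class = "widefield_result")
}

#' @export
print.widefield_result <- function(x, ...) {
  cat(sprintf("<widefield_result> %d ROIs (%dx%d) x %d samples @ %g Hz, %d regression bands\n",
              ncol(x$corrected), x$roi_dim[1], x$roi_dim[2], nrow(x$corrected),
              x$rate, nrow(x$steps)))
  invisible(x)
}

#' Extract one corrected ROI trace from a pipeline result
#' @param x A `widefield_result`.
#' @param roi ROI index (column), or `c(row, col)` in the ROI grid.
#' @param which `"corrected"`, `"uncorrected"`, or `"ref"`.
#' @return A [trace].
#' @export
pipeline_roi_trace <- function(x, roi = 1,
                               which = c("corrected", "uncorrected", "ref")) {
  which <- match.arg(which)
  stopifnot(inherits(x, "widefield_result"))
  if (length(roi) == 2) roi <- (roi[2] - 1) * x$roi_dim[1] + roi[1]
  M <- switch(which, corrected = x$corrected, uncorrected = x$uncorrected,
              ref = x$ref_dff)
  trace(M[, roi], x$rate, units = "dF/F")
}
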