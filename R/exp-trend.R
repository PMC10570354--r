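# Multi-term exponential photobleaching trends. The model is
#   trend(t) = offset + sum_i A_i * exp(lambda_i * t),   lambda_i < 0,
# fitted by variable projection: for trial decay rates the amplitudes and
# offset are the exact linear least-squares solution, and only the rates are
# optimised numerically (Nelder-Mead, multi-start over log-spaced rates).

trend_design <- function(tt, lambdas) {
  cbind(1, exp(outer(tt, lambdas)))
}

# Profile RSS for given decay rates; returns Inf for unusable rates.
trend_profile <- function(log_neg_lambda, tt, y) {
  lam <- -exp(log_neg_lambda)
  X <- trend_design(tt, lam)
  fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  r <- fit$residuals
  list(rss = sum(r * r), coef = fit$coefficients, lambdas = lam)
}

#' Fit a multi-term exponential trend to a trace
#'
#' Least-squares fit of `offset + sum A_i exp(lambda_i t)` over the samples not
#' excluded (e.g. stimulation windows are excluded when estimating a
#' photobleaching trend). Decay rates are constrained negative; 8 multi-starts
#' with log-spaced initial rates guard against local minima and the best fit by
#' residual sum of squares is returned.
#'
#' @param x A [trace].
#' @param exclude_windows List of `c(start, end)` windows (s) whose samples are
#'   excluded from the fit (stimulation periods).
#' @param n_terms Number of exponential terms, 1-3 (default 3).
#' @param n_starts Number of multi-start initialisations (default 8).
#' @return An object of class `exp_trend`: `n_terms`, `amplitudes`, `rates`
#'   (1/s, negative), `offset`, `fit_window_mask`, `rss`, and `degenerate`
#'   (TRUE when no start converged to a usable fit).
#' @export
fit_trend <- function(x, exclude_windows = list(), n_terms = 3, n_starts = 8) {
  stopifnot(inherits(x, "trace"), n_terms >= 1, n_terms <= 3)
  tt <- trace_times(x)
  keep <- rep(TRUE, length(tt))
  for (w in exclude_windows) keep[tt >= w[1] & tt < w[2]] <- FALSE
  if (sum(keep) < 10 * n_terms)
    stop("need at least ", 10 * n_terms, " retained samples to fit ", n_terms, " terms")
  ts <- tt[keep]; ys <- x$values[keep]
  t_ref <- ts[1]
  ts <- ts - t_ref          # rate estimation is better conditioned from t = 0
  dur <- max(ts) - min(ts)
  dt <- 1 / x$rate

  # near-constant trace: flat trend, no decay worth modelling
  if (stats::sd(ys) < 1e-12 * max(abs(mean(ys)), 1)) {
    return(structure(list(n_terms = 1L, amplitudes = 0, rates = -1 / dur,
                          offset = mean(ys), t_ref = t_ref,
                          fit_window_mask = keep, rss = 0, degenerate = FALSE),
                     class = "exp_trend"))
  }

  tau_lo <- max(5 * dt, dur / 500)
  tau_hi <- dur * 5
  best <- NULL
  set_starts <- lapply(seq_len(n_starts), function(i) {
    # log-spaced base time constant, terms separated by factors of ~6
    tau0 <- exp(log(tau_lo) + (i - 1) / max(1, n_starts - 1) * (log(tau_hi) - log(tau_lo)))
    taus <- tau0 * 6^(seq_len(n_terms) - 1)
    log(1 / pmin(taus, tau_hi * 10))
  })
  for (st in set_starts) {
    opt <- tryCatch(
      if (length(st) == 1) {
        stats::optim(st, function(p) trend_profile(p, ts, ys)$rss,
                     method = "Brent",
                     lower = log(1 / (tau_hi * 10)), upper = log(1 / tau_lo),
                     control = list(maxit = 500))
      } else {
        stats::optim(st, function(p) trend_profile(p, ts, ys)$rss,
                     method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
      },
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(structure(list(n_terms = as.integer(n_terms), amplitudes = rep(NA_real_, n_terms),
                          rates = rep(NA_real_, n_terms), offset = NA_real_,
                          t_ref = t_ref, fit_window_mask = keep, rss = Inf,
                          degenerate = TRUE),
                     class = "exp_trend"))
  }
  sol <- trend_profile(best$par, ts, ys)
  ord <- order(sol$lambdas)  # most negative (fastest) first
  structure(list(n_terms = as.integer(n_terms),
                 amplitudes = sol$coef[-1][ord],
                 rates = sol$lambdas[ord],
                 offset = sol$coef[1],
                 t_ref = t_ref,
                 fit_window_mask = keep,
                 rss = sol$rss,
                 degenerate = FALSE),
            class = "exp_trend")
}

#' @export
print.exp_trend <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<exp_trend> degenerate fit (no start converged)\n")
    return(invisible(x))
  }
  cat(sprintf("<exp_trend> %d term(s): offset %.4g + %s, rss %.4g\n",
              x$n_terms,
              paste(sprintf("%.4g*exp(%.4g t)", x$amplitudes, x$rates), collapse = " + "),
              x$rss))
  invisible(x)
}

#' Evaluate a fitted trend at given times
#' @param trend An `exp_trend` from [fit_trend()].
#' @param times Times in seconds.
#' @return Numeric vector of trend values.
#' @export
eval_trend <- function(trend, times) {
  stopifnot(inherits(trend, "exp_trend"))
  if (isTRUE(trend$degenerate)) stop("cannot evaluate a degenerate trend fit")
  ts <- times - trend$t_ref
  drop(trend_design(ts, trend$rates) %*% c(trend$offset, trend$amplitudes))
}

#' Divisive detrending of a trace or movie
#'
#' Removes a fitted photobleaching trend by division: `out(t) = data(t) /
#' trend(t)`. For movies, the paper's per-pixel convention is followed: the
#' shared fitted time constants are kept and per-pixel amplitudes (and offset)
#' are re-estimated by linear least squares before dividing.
#'
#' @param x A [trace] or [movie].
#' @param trend An `exp_trend` from [fit_trend()].
#' @param per_pixel For movies, re-fit per-pixel amplitudes with the shared
#'   rates (default TRUE).
#' @param mask Optional [pixel_mask] limiting movie detrending to foreground
#'   pixels (background pixels have no positive trend to divide by and are
#'   passed through unchanged).
#' @return Detrended object of the same type. Detrending data equal to the
#'   trend itself yields all-ones.
#' @export
detrend_divide <- function(x, trend, per_pixel = TRUE, mask = NULL) {
  stopifnot(inherits(trend, "exp_trend"))
  if (inherits(x, "trace")) {
    tv <- eval_trend(trend, trace_times(x))
    if (any(tv <= 0)) stop("trend is not positive over the record; cannot divide")
    return(trace(x$values / tv, x$rate, t0_offset = x$t0_offset,
                 units = paste0(x$units, "/trend"), polarity = x$polarity))
  }
  if (inherits(x, "movie")) {
    d <- dim(x$frames)
    tt <- (seq_len(d[1]) - 1) / x$rate
    flat <- matrix(x$frames, nrow = d[1])
    sel <- if (is.null(mask)) seq_len(d[2] * d[3]) else which(as.vector(mask_grid(mask)))
    if (per_pixel) {
      X <- trend_design(tt - trend$t_ref, trend$rates)
      coefs <- stats::lm.fit(X, flat[, sel, drop = FALSE])$coefficients
      coefs[is.na(coefs)] <- 0        # dropped collinear columns (equal rates)
      tv <- X %*% coefs                                 # per-pixel trends
    } else {
      tv <- matrix(eval_trend(trend, tt), nrow = d[1], ncol = length(sel))
    }
    if (any(tv <= 0)) stop("trend is not positive over the record; cannot divide")
    out <- flat
    out[, sel] <- flat[, sel, drop = FALSE] / tv
    return(structure(list(frames = array(out, d), rate = x$rate,
                          channel = x$channel, saturation_level = x$saturation_level),
                     class = "movie"))
  }
  stop("`x` must be a trace or a movie")
}
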