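# Exponential-with-onset kinetics. The response of a voltage indicator to a
# command-voltage step is modelled as a constant baseline up to a fitted onset
# time t0, followed by mono- or bi-exponential relaxation toward a plateau c:
#
#   mono:  F(t) = c + k*exp((t - t0)*lambda)              for t >  t0
#          F(t) = c + k                                   for t <= t0
#   dual:  F(t) = c + k*exp((t - t0)*lambda) + k2*exp((t - t0)*lambda2)  (t > t0)
#          F(t) = c + k + k2                                             (t <= t0)
#
# lambda, lambda2 < 0 are the negative reciprocal time constants
# (tau = -1/lambda). The onset t0 is fitted jointly with the other
# coefficients. Amplitudes and plateau are linear given (t0, rates), so the
# fitter uses variable projection: only (t0, log(-lambda)[, log(-lambda2)])
# are optimised numerically and the linear coefficients are solved exactly at
# every step.

#' Evaluate the exponential-with-onset model
#'
#' @param t Times (s).
#' @param pars Named list with `c`, `k`, `lambda`, `t0`, and optionally `k2`,
#'   `lambda2` for the dual model.
#' @return Model values at `t`.
#' @export
exp_onset_model <- function(t, pars) {
  p <- pars
  post <- t > p$t0
  y <- rep(p$c + p$k, length(t))
  y[post] <- p$c + p$k * exp((t[post] - p$t0) * p$lambda)
  if (!is.null(p$k2)) {
    y[!post] <- y[!post] + p$k2
    y[post] <- y[post] + p$k2 * exp((t[post] - p$t0) * p$lambda2)
  }
  y
}

# onset-exponential basis columns: 1 for t <= t0, exp((t-t0)*lambda) after
onset_basis <- function(t, t0, lambdas) {
  post <- t > t0
  sapply(lambdas, function(l) {
    e <- rep(1, length(t))
    e[post] <- exp((t[post] - t0) * l)
    e
  })
}

onset_profile <- function(par, t, y, order) {
  t0 <- par[1]
  lam <- -exp(par[-1])
  X <- cbind(1, onset_basis(t, t0, lam))
  fit <- tryCatch(stats::.lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf))
  r <- fit$residuals
  list(rss = sum(r * r), coef = fit$coefficients, lambdas = lam, t0 = t0)
}

#' Downsample a trace by block averaging
#'
#' Block-mean decimation by an integer factor (e.g. 80 kHz acquisition down to
#' 20 kHz before kinetics fitting). DC is preserved exactly for constant
#' traces.
#'
#' @param x A [trace].
#' @param target_rate Target rate in Hz; `rate / target_rate` must be an
#'   integer.
#' @return The decimated [trace]; its `t0_offset` points at the centre of the
#'   first averaging block.
#' @export
downsample <- function(x, target_rate) {
  stopifnot(inherits(x, "trace"))
  fac <- x$rate / target_rate
  if (abs(fac - round(fac)) > 1e-9 || fac < 1)
    stop("rate must be an integer multiple of target_rate")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(x)
  n <- (length(x$values) %/% fac) * fac
  v <- colMeans(matrix(x$values[seq_len(n)], nrow = fac))
  trace(v, target_rate, t0_offset = x$t0_offset + (fac - 1) / (2 * x$rate),
        units = x$units, polarity = x$polarity)
}

#' Divisive photobleaching correction from baseline windows
#'
#' Fits a three-term exponential trend using only the baseline segments (e.g.
#' the periods when the cell is held at its resting command voltage) and
#' removes it from the whole record by division.
#'
#' @param x A [trace].
#' @param baseline_windows List of `c(start, end)` windows (s) that are
#'   baseline; everything outside them is excluded from the trend fit. The
#'   windows must cover at least 10% of the record.
#' @param n_terms Trend terms (default 3).
#' @return The corrected [trace].
#' @export
correct_baseline_bleach <- function(x, baseline_windows, n_terms = 3) {
  stopifnot(inherits(x, "trace"), length(baseline_windows) >= 1)
  tt <- trace_times(x)
  inb <- rep(FALSE, length(tt))
  for (w in baseline_windows) inb[tt >= w[1] & tt < w[2]] <- TRUE
  if (mean(inb) < 0.10) stop("baseline windows must cover at least 10% of the record")
  # complement of the baseline, as exclusion windows for fit_trend
  r <- rle(!inb)
  ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
  excl <- lapply(which(r$values), function(i)
    c(tt[starts[i]], tt[ends[i]] + 1 / x$rate))
  trend <- fit_trend(x, exclude_windows = excl, n_terms = n_terms)
  detrend_divide(x, trend)
}

#' Fit the exponential-with-onset model to a step response
#'
#' Nonlinear least squares over `{c, k, (k2), lambda, (lambda2), t0}` on the
#' window around the nominal transition onset. The onset is fitted jointly
#' with the other coefficients via a multi-start grid (default 11 points
#' across +-10 ms around the nominal onset) combined with log-spaced initial
#' rates; the best fit by residual sum of squares is returned.
#'
#' @param x A [trace], typically bleach-corrected and downsampled to 20 kHz.
#' @param onset Nominal transition onset (s).
#' @param window Fit window relative to `onset`, default `c(-0.1, 1)` s.
#' @param model_order 1 (mono) or 2 (dual exponential).
#' @param t0_grid Number of onset multi-start points (default 11).
#' @param t0_span Half-width of the onset start grid (s, default 0.01).
#' @param tau_starts Initial fast time constants to try (s); defaults are
#'   log-spaced from 0.3 to 5 ms, with the slow component started at 15x the
#'   fast one for dual fits.
#' @return An object of class `exp_onset_fit` with components `model_order`,
#'   `c`, `k`, `k2`, `lambda`, `lambda2` (1/s), `t0` (s), `rss`, `tau_fast`,
#'   `tau_slow` (ms), `frac_fast` (%), `degenerate`, `noise_sd`, plus the data
#'   needed by `predict`/`residuals` methods. When the fitted amplitude is
#'   below the noise floor the fit is flagged degenerate and the time
#'   constants are `NA`.
#' @seealso [summarize_time_constants()], [select_model()]
#' @export
fit_exp_onset <- function(x, onset, window = c(-0.1, 1), model_order = 1,
                          t0_grid = 11, t0_span = 0.01,
                          tau_starts = c(3e-4, 1.2e-3, 5e-3)) {
  stopifnot(inherits(x, "trace"), model_order %in% c(1, 2))
  xs <- trace_window(x, onset + window[1], onset + window[2])
  tt <- trace_times(xs)
  y <- xs$values

  # noise floor from the pre-onset baseline (first differences are robust to
  # any residual slow trend)
  pre <- y[tt < onset - 1e-3]
  noise_sd <- if (length(pre) > 10) stats::sd(diff(pre)) / sqrt(2) else
    stats::sd(diff(y)) / sqrt(2)

  t0s <- if (t0_grid > 1) onset + seq(-t0_span, t0_span, length.out = t0_grid)
         else onset
  starts <- list()
  for (t0 in t0s) for (tau in tau_starts) {
    p <- c(t0, log(1 / tau))
    if (model_order == 2) p <- c(p, log(1 / (15 * tau)))
    starts[[length(starts) + 1]] <- p
  }
  # stage 1: short runs from every start on a decimated grid (start screening
  # only); stage 2: polish the best few on the full data
  stride <- max(1L, length(y) %/% 4000L)
  tc <- tt[seq(1, length(tt), by = stride)]
  yc <- y[seq(1, length(y), by = stride)]
  coarse <- lapply(starts, function(st)
    tryCatch(stats::optim(st, function(p) onset_profile(p, tc, yc, model_order)$rss,
                          method = "Nelder-Mead",
                          control = list(maxit = 60, reltol = 1e-8)),
             error = function(e) list(value = Inf, par = st)))
  vals <- vapply(coarse, function(o) o$value, numeric(1))
  keep <- order(vals)[seq_len(min(3, length(vals)))]
  best <- NULL
  for (i in keep) {
    opt <- tryCatch(stats::optim(coarse[[i]]$par,
                                 function(p) onset_profile(p, tt, y, model_order)$rss,
                                 method = "Nelder-Mead",
                                 control = list(maxit = 4000, reltol = 1e-15)),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("exponential-onset fit did not converge from any start")
  sol <- onset_profile(best$par, tt, y, model_order)

  cc <- sol$coef[1]
  ks <- sol$coef[-1]
  amp <- sum(abs(ks))
  scale <- max(abs(y), 1e-300)
  degenerate <- amp < max(3 * noise_sd, 1e-10 * scale)

  if (model_order == 2) {
    # order components fast first (more negative lambda = faster)
    ord <- order(sol$lambdas)
    lam <- sol$lambdas[ord]; ks <- ks[ord]
    fit <- list(model_order = 2L, c = cc, k = ks[1], k2 = ks[2],
                lambda = lam[1], lambda2 = lam[2], t0 = sol$t0, rss = sol$rss,
                tau_fast = -1000 / lam[1], tau_slow = -1000 / lam[2],
                frac_fast = 100 * abs(ks[1]) / (abs(ks[1]) + abs(ks[2])))
  } else {
    fit <- list(model_order = 1L, c = cc, k = ks[1], k2 = NULL,
                lambda = sol$lambdas[1], lambda2 = NULL, t0 = sol$t0,
                rss = sol$rss, tau_fast = -1000 / sol$lambdas[1],
                tau_slow = NA_real_, frac_fast = NA_real_)
  }
  if (degenerate) {
    fit$tau_fast <- NA_real_; fit$tau_slow <- NA_real_; fit$frac_fast <- NA_real_
  }
  fit$degenerate <- degenerate
  fit$noise_sd <- noise_sd
  fit$data <- list(time = tt, values = y)
  structure(fit, class = "exp_onset_fit")
}

#' @export
print.exp_onset_fit <- function(x, ...) {
  cat(sprintf("Exponential-with-onset fit (order %d)%s\n", x$model_order,
              if (x$degenerate) " [degenerate: amplitude below noise floor]" else ""))
  cat(sprintf("  plateau c = %.6g, onset t0 = %.6g s, rss = %.4g\n", x$c, x$t0, x$rss))
  if (!x$degenerate) {
    if (x$model_order == 2) {
      cat(sprintf("  tau_fast = %.4g ms (k = %.4g), tau_slow = %.4g ms (k2 = %.4g)\n",
                  x$tau_fast, x$k, x$tau_slow, x$k2))
      cat(sprintf("  fraction fast = %.1f%%\n", x$frac_fast))
    } else {
      cat(sprintf("  tau = %.4g ms (k = %.4g)\n", x$tau_fast, x$k))
    }
  }
  invisible(x)
}

#' @export
summary.exp_onset_fit <- function(object, ...) {
  out <- c(summarize_time_constants(object),
           list(model_order = object$model_order, c = object$c, t0 = object$t0,
                rss = object$rss, n = length(object$data$values),
                degenerate = object$degenerate))
  class(out) <- "summary.exp_onset_fit"
  out
}

#' @export
print.summary.exp_onset_fit <- function(x, ...) {
  cat(sprintf("order %d fit on %d samples: tau_fast %.4g ms", x$model_order, x$n,
              x$tau_fast))
  if (!is.na(x$tau_slow)) cat(sprintf(", tau_slow %.4g ms, %.1f%% fast",
                                      x$tau_slow, x$frac_fast))
  cat(sprintf(" (t0 %.5g s, rss %.4g)\n", x$t0, x$rss))
  invisible(x)
}

#' @export
coef.exp_onset_fit <- function(object, ...) {
  if (object$model_order == 2)
    c(c = object$c, k = object$k, k2 = object$k2,
      lambda = object$lambda, lambda2 = object$lambda2, t0 = object$t0)
  else
    c(c = object$c, k = object$k, lambda = object$lambda, t0 = object$t0)
}

#' @export
predict.exp_onset_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time
  exp_onset_model(times, object)
}

#' @export
fitted.exp_onset_fit <- function(object, ...) predict(object)

#' @export
residuals.exp_onset_fit <- function(object, ...)
  object$data$values - predict(object)

#' Report time constants and fraction fast from a fit
#'
#' `tau_i = -1000 / lambda_i` (ms); the fast component is the smaller tau;
#' the fraction fast is `100 * |k_fast| / (|k_fast| + |k_slow|)`. Mono fits
#' report `tau_fast` only (`tau_slow` and `frac_fast` are `NA`).
#'
#' @param fit An `exp_onset_fit`.
#' @return List with `tau_fast` (ms), `tau_slow` (ms or `NA`), `frac_fast`
#'   (percent or `NA`).
#' @export
summarize_time_constants <- function(fit) {
  stopifnot(inherits(fit, "exp_onset_fit"))
  if (fit$degenerate) stop("degenerate fit: time constants are undefined")
  list(tau_fast = fit$tau_fast, tau_slow = fit$tau_slow, frac_fast = fit$frac_fast)
}

#' Choose mono vs dual exponential model order
#'
#' Fits both orders and returns 2 only when the dual model improves the
#' small-sample-corrected AIC and both fitted components clear an amplitude
#' floor of 3x the baseline noise sd (parsimony rule).
#'
#' @inheritParams fit_exp_onset
#' @return List with `order` (1 or 2), both fits (`fit1`, `fit2`), and the
#'   AICc values.
#' @export
select_model <- function(x, onset, window = c(-0.1, 1), ...) {
  f1 <- fit_exp_onset(x, onset, window, model_order = 1, ...)
  f2 <- fit_exp_onset(x, onset, window, model_order = 2, ...)
  n <- length(f1$data$values)
  aicc <- function(rss, p) {
    n * log(rss / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  }
  a1 <- aicc(f1$rss, 4)   # c, k, lambda, t0
  a2 <- aicc(f2$rss, 6)
  floor_ok <- !f2$degenerate &&
    min(abs(f2$k), abs(f2$k2)) >= 3 * f2$noise_sd
  order <- if (a2 < a1 && floor_ok) 2L else 1L
  list(order = order, fit1 = f1, fit2 = f2, aicc = c(order1 = a1, order2 = a2))
}
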