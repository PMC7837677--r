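#' Compute dF/F0 from a raw fluorescence trace
#'
#' Normalises a raw fluorescence series to `(F - F0) / F0`, where the
#' baseline `F0` is the mean intensity over `baseline_ms` (default ~150 ms)
#' immediately before the first stimulus.
#'
#' @param trace A [fluor_trace()] with raw fluorescence values and at least
#'   one stimulus time.
#' @param baseline_ms Baseline averaging window before the first stimulus, ms.
#' @return A [fluor_trace()] with `unit = "dF/F0"`, `meta$F0` set, and the
#'   original metadata carried over.
#' @export
compute_dff <- function(trace, baseline_ms = 150) {
  stopifnot(inherits(trace, "fluor_trace"), length(trace$stim_times) >= 1)
  t1 <- trace$stim_times[1]
  bl <- trace$time_ms >= t1 - baseline_ms & trace$time_ms < t1
  if (!any(bl)) stop("no pre-stimulus samples inside the baseline window")
  f0 <- mean(trace$value[bl])
  if (!is.finite(f0) || f0 <= 0) stop("baseline F0 must be positive")
  meta <- trace$meta
  meta$F0 <- f0
  fluor_trace(trace$time_ms, (trace$value - f0) / f0, trace$stim_times,
              unit = "dF/F0", meta = meta)
}

# mono-exponential decay fit on (t, y); log-linear init refined by nls
.fit_monoexp <- function(t, y, tau0 = 40) {
  pos <- y > 0
  if (sum(pos) >= 3) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    tau0 <- -1 / stats::coef(lf)[2]
    a0 <- exp(stats::coef(lf)[1])
    if (!is.finite(tau0) || tau0 <= 0) { tau0 <- 40; a0 <- max(y) }
  } else a0 <- max(y)
  fit <- try(suppressWarnings(
    stats::nls(y ~ a * exp(-t / tau), start = list(a = a0, tau = tau0),
               control = stats::nls.control(warnOnly = TRUE))),
    silent = TRUE)
  if (inherits(fit, "try-error")) return(list(a = a0, tau = tau0))
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), tau = unname(cf["tau"]))
}

#' Paired-pulse amplitude ratio of a glutamate-sensor trace
#'
#' Measures the dF/F0 response amplitudes of a paired-pulse (50 ms interval)
#' trace. `A1` is the peak within the response window after pulse 1. For
#' pulse 2, the residual mono-exponential decay of response 1 (decay constant
#' fitted between the first peak and the second stimulus onset) is
#' extrapolated and subtracted before taking the peak, so `A2` is the genuine
#' second response. The ratio is oriented second/first, so facilitation gives
#' `PPR > 1`.
#'
#' @param trace A dF/F0 [fluor_trace()] (see [compute_dff()]) with exactly
#'   two stimuli 50 ms apart.
#' @param response_window Peak-search window after each stimulus, ms.
#' @param noise_floor Amplitudes below this dF/F0 value make the ratio
#'   undefined (`NA`).
#' @return List: `A1`, `A2`, `PPR_glu` (`NA` if `A1` is at/below the noise
#'   floor), `tau_decay` (fitted first-response decay, ms).
#' @export
paired_pulse_ratio_glu <- function(trace, response_window = c(2, 45),
                                   noise_floor = 0.02) {
  stopifnot(inherits(trace, "fluor_trace"))
  st <- trace$stim_times
  if (length(st) != 2 || abs(diff(st) - 50) > 1e-6)
    stop("expected exactly 2 stimuli 50 ms apart")
  t <- trace$time_ms; v <- trace$value
  w1 <- t >= st[1] + response_window[1] & t <= st[1] + response_window[2]
  a1 <- max(v[w1]); tpk1 <- t[w1][which.max(v[w1])]
  # fit first-response decay between its peak and the second stimulus onset
  seg <- t > tpk1 & t < st[2]
  fit <- if (sum(seg) >= 3) .fit_monoexp(t[seg] - tpk1, v[seg]) else
    list(a = a1, tau = 40)
  w2 <- t >= st[2] + response_window[1] & t <= st[2] + response_window[2]
  resid1 <- fit$a * exp(-(t[w2] - tpk1) / fit$tau)
  a2 <- max(v[w2] - resid1)
  ppr <- if (a1 <= noise_floor) NA_real_ else a2 / a1
  list(A1 = a1, A2 = a2, PPR_glu = ppr, tau_decay = fit$tau)
}

#' Fit five overlapping exponentials to a 20 Hz burst response
#'
#' Reconstructs the fast per-pulse amplitudes underlying a (possibly
#' frame-subsampled) dF/F0 burst response by fitting
#' `dff(t) = sum_i A_i exp(-(t - dt*(i-1)) / tau)` for `i = 1..5`
#' (each term active from its stimulus onset), with `dt = 50` ms for the
#' 20 Hz protocol. The decay constant `tau` is fitted first on the signal
#' tail after the fifth pulse; the amplitudes `A1..A5` then follow by linear
#' least squares with `tau` fixed. The burst facilitation indicator
#' `peak_slope` is the OLS slope of `A_i` against the stimulus index.
#'
#' @param trace A dF/F0 [fluor_trace()] with 5 stimuli at 20 Hz (50 ms
#'   apart); frame-scan traces with as few as two samples on the post-burst
#'   tail are accepted.
#' @param tail_from_ms Tail-fit start relative to the fifth stimulus, ms.
#' @return A list of class `burst_fit`: `A` (length 5), `tau`, `dt_stim`,
#'   `peak_slope`, `rss`, `fitted` (function of time in ms).
#' @export
fit_burst5 <- function(trace, tail_from_ms = 15) {
  stopifnot(inherits(trace, "fluor_trace"))
  st <- trace$stim_times
  if (length(st) != 5 || any(abs(diff(st) - 50) > 1e-6))
    stop("expected 5 stimuli at 20 Hz (50 ms apart)")
  t <- trace$time_ms; v <- trace$value
  tail <- t >= st[5] + tail_from_ms
  if (sum(tail) < 2) stop("need at least 2 samples on the post-burst tail")

  if (max(abs(v)) == 0) {
    fitted <- function(tt) rep(0, length(tt))
    return(structure(list(A = rep(0, 5), tau = NA_real_, dt_stim = 50,
                          peak_slope = 0, rss = 0, fitted = fitted),
                     class = "burst_fit"))
  }
  tf <- .fit_monoexp(t[tail] - st[5], v[tail])
  tau <- tf$tau
  if (!is.finite(tau) || tau <= 0) stop("tail fit did not yield a positive tau")

  # design matrix: component i active from its stimulus onset
  X <- vapply(1:5, function(i) {
    ifelse(t >= st[i], exp(-(t - st[i]) / tau), 0)
  }, numeric(length(t)))
  use <- t >= st[1]
  A <- stats::coef(stats::lm.fit(X[use, , drop = FALSE], v[use]))
  A <- as.numeric(A); A[is.na(A)] <- 0
  rss <- sum((v[use] - X[use, ] %*% A)^2)
  slope <- unname(stats::coef(stats::lm(A ~ I(1:5)))[2])
  fitted <- function(tt) {
    Xi <- vapply(1:5, function(i)
      ifelse(tt >= st[i], exp(-(tt - st[i]) / tau), 0), numeric(length(tt)))
    as.numeric(Xi %*% A)
  }
  structure(list(A = A, tau = tau, dt_stim = 50, peak_slope = slope,
                 rss = rss, fitted = fitted),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("burst_fit: A = %s, tau = %.1f ms, peak slope = %.4f /stim\n",
              paste(sprintf("%.3f", x$A), collapse = " "), x$tau,
              x$peak_slope))
  invisible(x)
}

#' Regression of burst peak slopes against distance
#'
#' Regresses the five-pulse `peak_slope` statistic of each bouton against its
#' distance; a positive trend indicates stronger burst facilitation at more
#' distal locations.
#'
#' @param fits List of `burst_fit` objects (from [fit_burst5()]).
#' @param distance_um Matching distances, micrometres.
#' @return A `trend_regression` (see [regress_trend()]).
#' @export
slope_vs_distance <- function(fits, distance_um) {
  slopes <- vapply(fits, function(f) f$peak_slope, numeric(1))
  regress_trend(distance_um, slopes)
}
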