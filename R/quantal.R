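#' Tabulate paired-pulse trial outcomes
#'
#' Counts the four paired outcomes (0,0), (0,1), (1,0), (1,1) over a sequence
#' of trials.
#'
#' @param outcomes A two-column matrix/data frame of 0/1 flags (`s1`, `s2`),
#'   or a list of length-2 vectors.
#' @return A list of class `paired_counts` with fields `n00, n01, n10, n11, N`.
#' @examples
#' count_outcomes(rbind(c(1, 0), c(0, 0), c(1, 1)))
#' @export
count_outcomes <- function(outcomes) {
  if (is.list(outcomes) && !is.data.frame(outcomes))
    outcomes <- do.call(rbind, outcomes)
  outcomes <- as.matrix(outcomes)
  if (nrow(outcomes) == 0) stop("empty outcome sequence")
  if (ncol(outcomes) != 2 || !all(outcomes %in% c(0, 1)))
    stop("outcomes must be two binary columns (s1, s2)")
  s1 <- outcomes[, 1]; s2 <- outcomes[, 2]
  res <- list(n00 = sum(s1 == 0 & s2 == 0),
              n01 = sum(s1 == 0 & s2 == 1),
              n10 = sum(s1 == 1 & s2 == 0),
              n11 = sum(s1 == 1 & s2 == 1))
  res$N <- res$n00 + res$n01 + res$n10 + res$n11
  structure(res, class = "paired_counts")
}

#' Optical quantal analysis release-probability estimators
#'
#' From paired-pulse success/failure counts computes:
#' \itemize{
#'   \item `P1 = (n10 + n11) / N` — first-pulse release probability (the
#'     single-synapse release probability Pr);
#'   \item `P2 = (n01 + n11) / N` — second-pulse release probability over all
#'     trials;
#'   \item `P2_star = n01 / (n00 + n01)` — second-pulse probability restricted
#'     to trials whose first pulse failed (robust to saturation of the
#'     indicator by a first-pulse response);
#'   \item `PPR = P2 / P1` and `PPR_star = P2_star / P1`.
#' }
#' Ratios that are undefined (`P1 = 0`) and `P2_star` with no first-pulse
#' failures (`n00 + n01 = 0`) are returned as `NA` with the corresponding
#' `undefined` flag set — mirroring the experimental practice of excluding
#' such synapses rather than silently reporting zero.
#'
#' @param counts A `paired_counts` (from [count_outcomes()]) or an outcome
#'   matrix accepted by it.
#' @return A list of class `quantal_estimates`: `P1, P2, P2_star, PPR,
#'   PPR_star, N, undefined` (character vector naming undefined statistics).
#' @examples
#' est <- estimate_release(count_outcomes(cbind(
#'   c(rep(1, 7), rep(0, 13)), c(rep(1, 3), rep(0, 4), rep(1, 6), rep(0, 7)))))
#' est$P1  # 0.35
#' @export
estimate_release <- function(counts) {
  if (!inherits(counts, "paired_counts")) counts <- count_outcomes(counts)
  N <- counts$N
  if (N < 1) stop("need at least one trial")
  p1 <- (counts$n10 + counts$n11) / N
  p2 <- (counts$n01 + counts$n11) / N
  undef <- character(0)
  if (counts$n00 + counts$n01 > 0) {
    p2s <- counts$n01 / (counts$n00 + counts$n01)
  } else {
    p2s <- NA_real_; undef <- c(undef, "P2_star")
  }
  if (p1 > 0) {
    ppr <- p2 / p1
    pprs <- if (is.na(p2s)) NA_real_ else p2s / p1
  } else {
    ppr <- NA_real_; pprs <- NA_real_
    undef <- c(undef, "PPR", "PPR_star")
  }
  if (is.na(pprs) && !"PPR_star" %in% undef && "P2_star" %in% undef)
    undef <- c(undef, "PPR_star")
  structure(list(P1 = p1, P2 = p2, P2_star = p2s, PPR = ppr,
                 PPR_star = pprs, N = N, undefined = undef),
            class = "quantal_estimates")
}

#' @export
print.quantal_estimates <- function(x, ...) {
  cat(sprintf("quantal_estimates (N = %d): P1 = %.3f, P2 = %.3f, P2* = %s, PPR = %s\n",
              x$N, x$P1, x$P2,
              ifelse(is.na(x$P2_star), "undef", sprintf("%.3f", x$P2_star)),
              ifelse(is.na(x$PPR), "undef", sprintf("%.3f", x$PPR))))
  invisible(x)
}

#' Classify one paired-pulse trial from a fluorescence trace
#'
#' Scores each pulse a success (1) if its measured amplitude — by default
#' the mean of the trace over the response window after the stimulus
#' (`statistic = "mean"`; `"peak"` uses the window maximum) — exceeds its
#' reference level by more than `k_sd` times the noise SD (default 2 SD, the separability criterion for
#' release successes versus failures). The first pulse is referenced to the
#' pre-stimulus baseline mean; the second pulse is referenced to the mean
#' over the `ref_ms` immediately before its own stimulus, so a second
#' response must rise above the decaying tail of a first response rather
#' than above the distant baseline. The noise SD is taken from the
#' pre-stimulus baseline window unless an externally estimated failure-trial
#' SD is supplied (see [classify_spine_trials()] for the iterative refinement
#' across a spine's trial set).
#'
#' @param trace A [fluor_trace()].
#' @param stim_times Length-2 stimulus times, ms (default from the trace).
#' @param baseline_window Length of the pre-stimulus baseline, ms.
#' @param k_sd Threshold in noise SDs (default 2).
#' @param response_window Length-2 search window after each stimulus, ms
#'   (default 5--45 ms post-stimulus).
#' @param ref_ms Averaging window immediately before the second stimulus
#'   used as its reference level, ms.
#' @param statistic Amplitude statistic: `"mean"` (window average; robust,
#'   the default) or `"peak"` (window maximum).
#' @param sd_override Optional externally estimated failure-noise SD.
#' @return Integer vector `c(s1, s2)`.
#' @export
classify_trial <- function(trace, stim_times = trace$stim_times,
                           baseline_window = 80, k_sd = 2,
                           response_window = c(5, 45),
                           ref_ms = 10,
                           statistic = c("mean", "peak"),
                           sd_override = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(trace, "fluor_trace"), length(stim_times) == 2)
  t <- trace$time_ms; v <- trace$value
  if (stim_times[1] - baseline_window < min(t))
    baseline_window <- stim_times[1] - min(t)
  if (baseline_window <= 0) stop("baseline window precedes the trace start")
  if (max(stim_times) + response_window[2] > max(t))
    stop("response window extends past the trace end")
  bl <- t >= stim_times[1] - baseline_window & t < stim_times[1]
  mu <- mean(v[bl])
  sd_noise <- if (is.null(sd_override)) stats::sd(v[bl]) else sd_override
  out <- integer(2)
  for (k in 1:2) {
    win <- t >= stim_times[k] + response_window[1] &
      t <= stim_times[k] + response_window[2]
    ref <- if (k == 1) mu else {
      pre <- t >= stim_times[k] - ref_ms & t < stim_times[k]
      if (any(pre)) mean(v[pre]) else mu
    }
    amp <- if (statistic == "mean") mean(v[win]) else max(v[win])
    out[k] <- as.integer(amp - ref > k_sd * sd_noise)
  }
  out
}

#' Classify all trials of one spine with failure-SD refinement
#'
#' First pass: every trial is classified against the baseline-noise SD.
#' Second pass: the noise SD is re-estimated from the response windows of the
#' trials classified as first-pulse failures (the SD of the signal during
#' release failures), and classification is re-run once against that SD. One
#' refinement pass keeps the procedure deterministic.
#'
#' @param traces List of [fluor_trace()] objects for one spine.
#' @inheritParams classify_trial
#' @return Integer matrix with columns `s1`, `s2`, one row per trial.
#' @export
classify_spine_trials <- function(traces, stim_times = NULL,
                                  baseline_window = 80, k_sd = 2,
                                  response_window = c(5, 45)) {
  stopifnot(length(traces) > 0)
  if (is.null(stim_times)) stim_times <- traces[[1]]$stim_times
  pass1 <- t(vapply(traces, classify_trial, integer(2),
                    stim_times = stim_times, baseline_window = baseline_window,
                    k_sd = k_sd, response_window = response_window))
  fails <- which(pass1[, 1] == 0L)
  if (length(fails) >= 3) {
    resp <- unlist(lapply(traces[fails], function(tr) {
      w <- tr$time_ms >= stim_times[1] + response_window[1] &
        tr$time_ms <= stim_times[1] + response_window[2]
      tr$value[w]
    }))
    sd_fail <- stats::sd(resp)
    pass2 <- t(vapply(traces, classify_trial, integer(2),
                      stim_times = stim_times,
                      baseline_window = baseline_window, k_sd = k_sd,
                      response_window = response_window,
                      sd_override = sd_fail))
    colnames(pass2) <- c("s1", "s2")
    return(pass2)
  }
  colnames(pass1) <- c("s1", "s2")
  pass1
}

#' Per-spine quantal estimates for a whole dataset
#'
#' Applies [count_outcomes()] and [estimate_release()] to every spine of a
#' `spine_dataset` (or a long trial data frame) and returns a tidy per-spine
#' table joined with the spine metadata.
#'
#' @param dataset A `spine_dataset` or a data frame with columns
#'   `spine_id, s1, s2` (optionally `distance_um` etc.).
#' @return Data frame: one row per spine with `P1, P2, P2_star, PPR, PPR_star,
#'   N` plus any spine metadata present.
#' @export
estimate_dataset <- function(dataset) {
  if (inherits(dataset, "spine_dataset")) {
    trials <- dataset$trials; spines <- dataset$spines
  } else {
    trials <- dataset
    meta_cols <- setdiff(names(trials), c("trial_idx", "s1", "s2"))
    spines <- unique(trials[, meta_cols, drop = FALSE])
  }
  est <- lapply(split(trials, trials$spine_id), function(d) {
    e <- estimate_release(count_outcomes(cbind(d$s1, d$s2)))
    data.frame(spine_id = d$spine_id[1], P1 = e$P1, P2 = e$P2,
               P2_star = e$P2_star, PPR = e$PPR, PPR_star = e$PPR_star,
               N = e$N)
  })
  out <- do.call(rbind, est)
  rownames(out) <- NULL
  merge(spines, out, by = "spine_id")
}
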