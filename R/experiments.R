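#' Configuration for an in-silico synaptic integration experiment
#'
#' Bundles the protocol settings shared by [run_paired_pulse()],
#' [run_burst5()] and [run_io_curve()]. Conditions compared within one call
#' share the same master seed, so synapse placements and release draws are
#' matched run-by-run (paired comparisons are valid by construction and every
#' number is bit-reproducible given `master_seed`).
#'
#' @param conditions Character vector drawn from `"uniform"`, `"pr_trend"`,
#'   `"pr_and_density_trend"`. `"uniform"` uses P1 = 0.36 / P2 = 0.77
#'   everywhere; the trend conditions distribute P1/P2 along the distance
#'   regressions with the population mean P1 rescaled to 0.36 so overall
#'   input efficacy is matched.
#' @param n_runs Runs per condition (default 100); synapse placement is
#'   redrawn every run.
#' @param n_synapses Synapses per run (default 50), placed 40--350
#'   micrometres from the soma.
#' @param A Conductance scale, uS. On the synthetic cell the defaults are
#'   1e-4 (subthreshold) and 1e-3 (spiking), calibrated so the mean
#'   paired-pulse EPSP sits at the ~3 mV operating point of the reference
#'   simulations and the input-output curve stays graded (no depolarisation
#'   block) over the physiological input range; on an imported
#'   reconstruction with dense active conductances use the reference values
#'   0.002 and 0.06.
#' @param stp Use the short-term-plasticity engine for trains of >= 3 spikes
#'   (paired-pulse protocols always use the explicit P1/P2 fields).
#' @param master_seed Integer master seed.
#' @param morph A `dendrite_morphology` (default: [generate_morphology()]).
#' @param max_seg_len Spatial discretisation, micrometres.
#' @param dt Time step, ms.
#' @param duration_ms Simulated protocol length for Poisson drive, ms.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(conditions = c("uniform", "pr_trend"),
                              n_runs = 100, n_synapses = 50, A = 1e-4,
                              stp = FALSE, master_seed = 1,
                              morph = NULL, max_seg_len = 10, dt = 0.025,
                              duration_ms = 2000) {
  conditions <- match.arg(conditions,
                          c("uniform", "pr_trend", "pr_and_density_trend"),
                          several.ok = TRUE)
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (is.null(morph)) morph <- generate_morphology()
  structure(list(conditions = conditions, n_runs = n_runs,
                 n_synapses = n_synapses, A = A, stp = stp,
                 master_seed = as.integer(master_seed), morph = morph,
                 max_seg_len = max_seg_len, dt = dt,
                 duration_ms = duration_ms),
            class = "experiment_config")
}

.condition_modes <- function(condition) {
  switch(condition,
         uniform = list(pr = "uniform", density = "uniform", rescale = FALSE),
         pr_trend = list(pr = "trend", density = "uniform", rescale = TRUE),
         pr_and_density_trend = list(pr = "trend", density = "trend",
                                     rescale = TRUE),
         stop("unknown condition: ", condition))
}

.run_seeds <- function(master_seed, n_runs) {
  old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
  set.seed(master_seed)
  list(place = sample.int(1e9L, n_runs), release = sample.int(1e9L, n_runs))
}

#' Paired-pulse condition comparison
#'
#' Simulates `n_runs` paired-pulse trials (two synchronous afferent volleys
#' 50 ms apart) per condition at the subthreshold conductance scale. Each run
#' places the 50 synapses afresh, samples stochastic release from the
#' per-synapse (P1, P2) fields, integrates the cable model and measures the
#' somatic EPSP amplitudes (first pulse relative to rest, second relative to
#' the voltage at its onset) and their ratio. Runs in which a spike is
#' detected at this subthreshold scale are flagged and excluded with a
#' warning.
#'
#' @param config An [experiment_config()] at the subthreshold scale.
#' @return An object of class `protocol_result`: list with `per_run` (data
#'   frame: condition, run, epsp1, epsp2, ppr, spike), `summary` (per
#'   condition mean/SEM), and `config` echoes.
#' @export
run_paired_pulse <- function(config = experiment_config()) {
  comps <- discretise(config$morph, config$max_seg_len, cable_params())
  seeds <- .run_seeds(config$master_seed, config$n_runs)
  t1 <- 20; t2 <- 70
  rows <- list()
  for (cond in config$conditions) {
    modes <- .condition_modes(cond)
    for (r in seq_len(config$n_runs)) {
      pop <- place_synapses(comps, n = config$n_synapses,
                            pr_mode = modes$pr, density_mode = modes$density,
                            A = config$A, rescale_mean = modes$rescale,
                            seed = seeds$place[r])
      rel <- sample_paired_release(pop, seed = seeds$release[r])
      ev <- .release_events(pop, list(t1, t2),
                            list(rel$release1, rel$release2))
      tr <- simulate_cable(comps, ev, duration = 160, dt = config$dt,
                           record_every = 4L)
      e1 <- epsp_amplitude(tr, t1, window = t2 - t1 - 1, ref = "rest")
      e2 <- epsp_amplitude(tr, t2, window = 50, ref = "onset")
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, run = r, epsp1 = as.numeric(e1),
        epsp2 = as.numeric(e2), ppr = as.numeric(e2) / as.numeric(e1),
        spike = attr(e1, "spike") || attr(e2, "spike"))
    }
  }
  per_run <- do.call(rbind, rows)
  if (any(per_run$spike)) {
    warning(sum(per_run$spike),
            " run(s) produced a spike at subthreshold scale; excluded")
    per_run <- per_run[!per_run$spike, ]
  }
  .protocol_result(per_run, "paired_pulse", config,
                   metrics = c("epsp1", "epsp2", "ppr"))
}

.release_events <- function(pop, times, flags, tau1 = 1, tau2 = 20) {
  pieces <- lapply(seq_along(times), function(k) {
    idx <- which(flags[[k]])
    if (!length(idx)) return(NULL)
    data.frame(comp = pop$comp[idx], onset = times[[k]],
               gmax_uS = pop$gm_uS[idx], tau1 = tau1, tau2 = tau2,
               erev_mV = 0, x_um = pop$x_um[idx], normalise = TRUE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- conductance_event(1L, 0, 0)[0, ]
  out
}

#' Five-pulse burst voltage-transfer comparison
#'
#' Simulates 20 Hz five-pulse bursts with the short-term-plasticity engine
#' active at every synapse and integrates the somatic depolarisation over the
#' burst window (the voltage-transfer metric, mV ms).
#'
#' Two burst plasticity modes are available. `"slope_trend"` (default)
#' encodes the glutamate-imaging observation that the five-pulse peak slope
#' grows with distance: the engine is calibrated per synapse so its 50 ms
#' two-spike ratio equals `1 + s(x)`, where `s(x)` is the relative per-pulse
#' amplitude slope from `burst_slope_profile` (the uniform condition uses the
#' population-mean slope, so the conditions are matched in average burst
#' drive). `"paired_consistency"` instead calibrates the engine to the
#' synapse's paired-pulse field ratio P2/P1.
#'
#' @param config An [experiment_config()] (subthreshold scale; the STP
#'   engine is always on for this protocol).
#' @param burst_mode `"slope_trend"` or `"paired_consistency"`.
#' @param burst_slope_profile `c(slope_per_um, intercept)` of the five-pulse
#'   peak-slope trend in dF/F0 per stimulus, relative to `peak_dff`; defaults
#'   match [generate_iglu_dataset()].
#' @param peak_dff Reference first-pulse amplitude used to express the slope
#'   as a relative per-pulse gain.
#' @return A `protocol_result` with per-run `transfer` (mV ms) and `epsp1`.
#' @export
run_burst5 <- function(config = experiment_config(),
                       burst_mode = c("slope_trend", "paired_consistency"),
                       burst_slope_profile = c(2e-4, -8e-3),
                       peak_dff = 0.37) {
  burst_mode <- match.arg(burst_mode)
  comps <- discretise(config$morph, config$max_seg_len, cable_params())
  seeds <- .run_seeds(config$master_seed, config$n_runs)
  t1 <- 20; stim <- t1 + 50 * (0:4)
  duration <- max(stim) + 150
  rel_slope <- function(x)
    (burst_slope_profile[2] + burst_slope_profile[1] * x) / peak_dff
  mean_slope <- rel_slope(195)   # population mean over the 40-350 um range
  rows <- list()
  for (cond in config$conditions) {
    modes <- .condition_modes(cond)
    for (r in seq_len(config$n_runs)) {
      pop <- place_synapses(comps, n = config$n_synapses,
                            pr_mode = modes$pr, density_mode = modes$density,
                            A = config$A, rescale_mean = modes$rescale,
                            seed = seeds$place[r])
      # per-synapse release probabilities over the burst via the calibrated
      # facilitation/depression engine
      pmat <- vapply(seq_len(nrow(pop)), function(i) {
        target <- if (burst_mode == "paired_consistency") {
          pop$p2[i] / pop$p1[i]
        } else if (modes$pr == "trend") {
          1 + max(0, rel_slope(pop$x_um[i]))
        } else {
          1 + max(0, mean_slope)
        }
        stp <- stp_calibrate_ppr(target)
        stp_evolve(stim, pop$p1[i], stp)
      }, numeric(length(stim)))
      old <- .Random.seed_exists()
      set.seed(seeds$release[r])
      draws <- matrix(stats::runif(length(stim) * nrow(pop)),
                      nrow = length(stim))
      old()
      ev <- .release_events(pop, as.list(stim),
                            lapply(seq_along(stim),
                                   function(k) draws[k, ] < pmat[k, ]))
      tr <- simulate_cable(comps, ev, duration = duration, dt = config$dt,
                           record_every = 4L)
      rest <- tr$vm[1, 1]   # stabilised pre-protocol resting potential
      w <- tr$time_ms >= t1 & tr$time_ms <= max(stim) + 100
      transfer <- sum(diff(tr$time_ms[w]) *
                        (utils::head(tr$vm[w, 1] - rest, -1) +
                           utils::tail(tr$vm[w, 1] - rest, -1)) / 2)
      e1 <- epsp_amplitude(tr, t1, window = 49, ref = "rest")
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, run = r, transfer = transfer,
        epsp1 = as.numeric(e1), spike = attr(e1, "spike"))
    }
  }
  per_run <- do.call(rbind, rows)
  .protocol_result(per_run, "burst5", config, metrics = c("transfer", "epsp1"))
}

#' Input-output spiking-rate curves under Poisson afferent drive
#'
#' Drives every synapse with an independent homogeneous Poisson spike train
#' at the given per-axon rate, at the spiking conductance scale with the
#' Na/K mechanism enabled, and measures the somatic output spike rate. With
#' `config$stp = TRUE` the per-spike release probabilities follow the
#' calibrated facilitation/depression recursion; otherwise release at every
#' afferent spike is Bernoulli with the synapse's P1.
#'
#' @param config An [experiment_config()] at the spiking scale (`A = 1e-3`
#'   on the synthetic cell).
#' @param rates_hz Per-axon input rates to test, Hz.
#' @return A data frame of class `io_curve`: `condition, rate_hz, run,
#'   out_hz` plus a `summary` attribute (mean +/- SEM per condition and
#'   rate).
#' @export
run_io_curve <- function(config = experiment_config(A = 1e-3),
                         rates_hz = c(5, 10, 20, 50)) {
  params <- cable_params(active = TRUE)
  comps <- discretise(config$morph, config$max_seg_len, params)
  seeds <- .run_seeds(config$master_seed, config$n_runs)
  rows <- list()
  for (cond in config$conditions) {
    modes <- .condition_modes(cond)
    for (rate in rates_hz) {
      for (r in seq_len(config$n_runs)) {
        pop <- place_synapses(comps, n = config$n_synapses,
                              pr_mode = modes$pr,
                              density_mode = modes$density,
                              A = config$A, rescale_mean = modes$rescale,
                              seed = seeds$place[r])
        old <- .Random.seed_exists()
        set.seed((seeds$release[r] + round(rate * 1000)) %% 2147483647L)
        ev_list <- lapply(seq_len(nrow(pop)), function(i) {
          st <- poisson_train(rate, config$duration_ms)
          if (!length(st)) return(NULL)
          p <- if (config$stp)
            stp_evolve(st, pop$p1[i],
                       stp_calibrate_ppr(pop$p2[i] / pop$p1[i]))
          else rep(pop$p1[i], length(st))
          rel <- stats::runif(length(st)) < p
          if (!any(rel)) return(NULL)
          data.frame(comp = pop$comp[i], onset = st[rel],
                     gmax_uS = pop$gm_uS[i], tau1 = 1, tau2 = 20,
                     erev_mV = 0, x_um = pop$x_um[i], normalise = TRUE)
        })
        old()
        ev <- do.call(rbind, ev_list)
        tr <- simulate_cable(comps, ev, duration = config$duration_ms,
                             dt = config$dt, record_every = 8L)
        nsp <- length(detect_spikes(tr))
        rows[[length(rows) + 1]] <- data.frame(
          condition = cond, rate_hz = rate, run = r,
          out_hz = nsp / (config$duration_ms / 1000))
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(out_hz ~ condition + rate_hz, out, function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v))))
  summ <- data.frame(condition = agg$condition, rate_hz = agg$rate_hz,
                     mean_out_hz = agg$out_hz[, "mean"],
                     sem_out_hz = agg$out_hz[, "sem"])
  attr(out, "summary") <- summ
  class(out) <- c("io_curve", "data.frame")
  out
}

.protocol_result <- function(per_run, protocol, config, metrics) {
  summ <- do.call(rbind, lapply(split(per_run, per_run$condition), function(d) {
    s <- lapply(metrics, function(m)
      c(mean = mean(d[[m]]), sem = stats::sd(d[[m]]) / sqrt(nrow(d))))
    names(s) <- metrics
    data.frame(condition = d$condition[1], n = nrow(d),
               t(unlist(s)))
  }))
  rownames(summ) <- NULL
  structure(list(per_run = per_run, summary = summ, protocol = protocol,
                 metrics = metrics, conditions = config$conditions,
                 n_runs = config$n_runs, master_seed = config$master_seed),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("protocol_result:", x$protocol, "-", paste(x$conditions, collapse = " vs "),
      sprintf("(%d runs)\n", x$n_runs))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Summarise and compare protocol conditions
#'
#' Computes, for each metric, condition means with SEM, the percentage
#' difference of every condition relative to the reference (first) condition,
#' and the paired two-sided p-value (runs are matched across conditions by
#' construction).
#'
#' @param result A `protocol_result`.
#' @param test `"t"` or `"wilcoxon"` (see [compare_paired()]).
#' @param reference Reference condition (default the first, typically
#'   `"uniform"`).
#' @return Data frame: `metric, condition, mean, sem, pct_diff, p_value`.
#' @export
summarise_protocol <- function(result, test = c("t", "wilcoxon"),
                               reference = NULL) {
  test <- match.arg(test)
  pr <- result$per_run
  conds <- unique(pr$condition)
  if (is.null(reference)) reference <- conds[1]
  runs_ok <- Reduce(intersect, lapply(split(pr$run, pr$condition), unique))
  pr <- pr[pr$run %in% runs_ok, ]
  out <- list()
  for (m in result$metrics) {
    ref <- pr[pr$condition == reference, ]
    ref <- ref[order(ref$run), ]
    for (cond in conds) {
      d <- pr[pr$condition == cond, ]
      d <- d[order(d$run), ]
      if (nrow(d) != nrow(ref)) stop("mismatched run counts between conditions")
      pval <- if (cond == reference) NA_real_ else
        compare_paired(d[[m]], ref[[m]], test = test)
      out[[length(out) + 1]] <- data.frame(
        metric = m, condition = cond, mean = mean(d[[m]]),
        sem = stats::sd(d[[m]]) / sqrt(nrow(d)),
        pct_diff = 100 * (mean(d[[m]]) - mean(ref[[m]])) / mean(ref[[m]]),
        p_value = pval)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
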