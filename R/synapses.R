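#' Distance-dependent release-probability profile
#'
#' Trend mode returns the experimental regression `P1(x) = 0.18 + 0.0012 x`
#' (x in micrometres from the soma); uniform mode returns the population
#' average 0.36 everywhere. Values are clipped to [0, 1].
#'
#' @param x Path distance(s) from the soma, micrometres (>= 0).
#' @param mode `"trend"` or `"uniform"`.
#' @return P1 value(s).
#' @export
pr_profile <- function(x, mode = c("trend", "uniform")) {
  mode <- match.arg(mode)
  if (any(x < 0)) stop("x must be non-negative")
  if (mode == "uniform") return(rep(0.36, length(x)))
  pmin(1, pmax(0, 0.18 + 0.0012 * x))
}

#' Distance-dependent second-pulse release probability
#'
#' Trend mode: `P2(x) = (0.18 + 0.0012 x) * (3.31 - 0.0074 x)`, i.e. the P1
#' regression times the paired-pulse-ratio regression; uniform mode returns
#' 0.77. Clipped to [0, 1].
#'
#' @inheritParams pr_profile
#' @return P2 value(s).
#' @export
p2_profile <- function(x, mode = c("trend", "uniform")) {
  mode <- match.arg(mode)
  if (any(x < 0)) stop("x must be non-negative")
  if (mode == "uniform") return(rep(0.77, length(x)))
  pmin(1, pmax(0, (0.18 + 0.0012 * x) * (3.31 - 0.0074 * x)))
}

#' Distance-dependent peak synaptic conductance
#'
#' `Gm(x) = A * (0.51 + 0.002 x)` uS: synaptic strength grows centrifugally,
#' partially offsetting dendritic attenuation. `A = 0.002` uS is the
#' subthreshold scale, `A = 0.06` uS the spiking scale.
#'
#' @param x Path distance(s), micrometres.
#' @param A Scale factor, uS (> 0).
#' @return Conductance(s), uS.
#' @export
gm_profile <- function(x, A) {
  if (A <= 0) stop("A must be positive")
  A * (0.51 + 0.002 * x)
}

#' Place a stochastic synapse population on a morphology
#'
#' Distributes `n` synapses over the dendritic tree at path distances within
#' `x_range`, either uniformly or following a linearly increasing density
#' (the synaptic density trend; default doubles from 40 to 350 micrometres).
#' Each synapse receives its `P1`, `P2` (from [pr_profile()]/[p2_profile()])
#' and `Gm` (from [gm_profile()]). With `rescale_mean = TRUE` the P1 and P2
#' fields are scaled multiplicatively so the realised population mean P1 is
#' exactly `target_mean` (0.36), keeping the overall synaptic input efficacy
#' matched between conditions while preserving the relative PPR profile.
#'
#' The placement is redrawn from the same density at every trial of an
#' experiment (fresh placement per run), with matched seeds across compared
#' conditions.
#'
#' @param comps A `cable_compartments` (see [discretise()]).
#' @param n Number of synapses (default 50).
#' @param x_range Placement range, micrometres (default `c(40, 350)`).
#' @param pr_mode `"uniform"` or `"trend"` P1/P2 profile.
#' @param density_mode `"uniform"` or `"trend"` placement density.
#' @param A Conductance scale, uS.
#' @param rescale_mean Rescale P1 (and P2) so mean(P1) is exactly
#'   `target_mean`.
#' @param target_mean Target population mean P1 (default 0.36).
#' @param density_trend `c(intercept, slope_per_um)` of the un-normalised
#'   linear placement density used when `density_mode = "trend"`.
#' @param seed Optional integer seed.
#' @return An object of class `synapse_population`: data frame `x_um, comp,
#'   gm_uS, p1, p2` with the configuration kept as attributes.
#' @export
place_synapses <- function(comps, n = 50, x_range = c(40, 350),
                           pr_mode = c("uniform", "trend"),
                           density_mode = c("uniform", "trend"),
                           A = 0.002, rescale_mean = FALSE,
                           target_mean = 0.36,
                           density_trend = c(1, 1 / 270),
                           seed = NULL) {
  pr_mode <- match.arg(pr_mode)
  density_mode <- match.arg(density_mode)
  if (max(comps$x_um) < x_range[2] - 1e-9)
    stop("morphology does not reach ", x_range[2], " um")
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
    set.seed(as.integer(seed))
  }
  if (n == 0) {
    pop <- data.frame(x_um = numeric(0), comp = integer(0),
                      gm_uS = numeric(0), p1 = numeric(0), p2 = numeric(0))
  } else {
    if (density_mode == "uniform") {
      x <- stats::runif(n, x_range[1], x_range[2])
    } else {
      # inverse-CDF sampling from the linear density a + b x on x_range
      a <- density_trend[1]; b <- density_trend[2]
      u <- stats::runif(n)
      F1 <- a * x_range[1] + b * x_range[1]^2 / 2
      F2 <- a * x_range[2] + b * x_range[2]^2 / 2
      Fu <- F1 + u * (F2 - F1)
      x <- (-a + sqrt(a^2 + 2 * b * Fu)) / b
    }
    p1 <- pr_profile(x, pr_mode)
    p2 <- p2_profile(x, pr_mode)
    if (rescale_mean) {
      sc <- target_mean / mean(p1)
      p1 <- pmin(1, p1 * sc)
      p2 <- pmin(1, p2 * sc)
    }
    pop <- data.frame(x_um = x,
                      comp = comp_at_distance(comps, x, types = 4L),
                      gm_uS = gm_profile(x, A), p1 = p1, p2 = p2)
  }
  attr(pop, "pr_mode") <- pr_mode
  attr(pop, "density_mode") <- density_mode
  attr(pop, "A") <- A
  attr(pop, "rescale_mean") <- rescale_mean
  class(pop) <- c("synapse_population", "data.frame")
  pop
}

#' Sample one paired-pulse stochastic release pattern
#'
#' Pulse-1 flags are Bernoulli(`p1_i`), pulse-2 flags Bernoulli(`p2_i`),
#' independent across synapses and across the two pulses (only the marginal
#' second-pulse probability is specified by the model).
#'
#' @param pop A `synapse_population`.
#' @param seed Optional integer seed (same seed, same flags).
#' @return List with logical vectors `release1`, `release2`.
#' @export
sample_paired_release <- function(pop, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
    set.seed(as.integer(seed))
  }
  list(release1 = stats::runif(nrow(pop)) < pop$p1,
       release2 = stats::runif(nrow(pop)) < pop$p2)
}

#' Short-term plasticity parameters
#'
#' Facilitation/depression state model: utilisation `u` rests at `U`, is
#' incremented by `f_inc * (1 - u)` after each release-triggering spike and
#' relaxes back with `tau_facil`; resources `R` are depleted by the utilised
#' fraction and recover with `tau_rec`. The per-spike release probability is
#' `base_P * u R / U`, normalised so an isolated spike releases with exactly
#' `base_P`.
#'
#' @param U Baseline utilisation, in (0, 1].
#' @param f_inc Facilitation increment per spike, in [0, 1).
#' @param tau_facil Facilitation decay, ms (> 0).
#' @param tau_rec Resource recovery, ms (> 0).
#' @return A list of class `stp_params`.
#' @export
stp_params <- function(U = 0.2, f_inc = 0.25, tau_facil = 100, tau_rec = 60) {
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (f_inc < 0 || f_inc >= 1) stop("f_inc must be in [0, 1)")
  if (tau_facil <= 0 || tau_rec <= 0) stop("time constants must be positive")
  structure(list(U = U, f_inc = f_inc, tau_facil = tau_facil,
                 tau_rec = tau_rec), class = "stp_params")
}

#' Evolve release probabilities over a spike train
#'
#' Runs the facilitation-depression recursion over a sorted spike train and
#' returns the release probability at each spike. The first two discharges
#' express the prominent facilitation/depression transient; for constant-rate
#' trains the probabilities settle within ~4 spikes to a frequency-dependent
#' steady state. With both time constants near zero the model degenerates to
#' a constant `base_P`.
#'
#' @param spike_times Sorted spike times, ms.
#' @param base_P Baseline (isolated-spike) release probability.
#' @param params An [stp_params()].
#' @return Numeric vector of per-spike release probabilities (clipped to
#'   [0, 1]).
#' @export
stp_evolve <- function(spike_times, base_P, params = stp_params()) {
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  nsp <- length(spike_times)
  if (nsp == 0) return(numeric(0))
  u <- params$U; R <- 1
  p <- numeric(nsp)
  tprev <- NA_real_
  for (k in seq_len(nsp)) {
    if (k > 1) {
      dtk <- spike_times[k] - tprev
      u <- params$U + (u - params$U) * exp(-dtk / params$tau_facil)
      R <- 1 - (1 - R) * exp(-dtk / params$tau_rec)
    }
    p[k] <- min(1, max(0, base_P * u * R / params$U))
    R <- R * (1 - u)
    u <- u + params$f_inc * (1 - u)
    tprev <- spike_times[k]
  }
  p
}

#' Calibrate STP parameters to a paired-pulse ratio at 50 ms
#'
#' Paired-pulse consistency mode: chooses the facilitation increment (for
#' facilitating targets, PPR >= 1, at fixed `U`) or the baseline utilisation
#' (for depressing targets, PPR < 1, with `f_inc = 0`) so that the model's
#' two-spike prediction at a 50 ms interval equals `target_ppr` — e.g. the
#' distance-dependent paired-pulse regression `3.31 - 0.0074 x` evaluated at
#' each synapse. For trains of three or more spikes the calibrated recursion
#' supplies the later-pulse probabilities.
#'
#' @param target_ppr Desired ratio `p2 / p1` at a 50 ms interval.
#' @param U Baseline utilisation used for facilitating targets.
#' @param tau_facil,tau_rec Time constants, ms.
#' @param dt_ms Inter-spike interval of the calibration pair (default 50).
#' @return An [stp_params()] whose two-spike prediction matches `target_ppr`.
#' @export
stp_calibrate_ppr <- function(target_ppr, U = 0.2, tau_facil = 100,
                              tau_rec = 60, dt_ms = 50) {
  if (target_ppr <= 0) stop("target_ppr must be positive")
  ef <- exp(-dt_ms / tau_facil)
  er <- exp(-dt_ms / tau_rec)
  if (target_ppr >= 1) {
    # PPR = (U + f(1-U) ef) (1 - U er) / U, linear in f
    f <- (target_ppr * U / (1 - U * er) - U) / ((1 - U) * ef)
    f <- min(0.999, max(0, f))
    stp_params(U = U, f_inc = f, tau_facil = tau_facil, tau_rec = tau_rec)
  } else {
    # with f = 0: PPR = 1 - U er; solve for U
    u <- (1 - target_ppr) / er
    u <- min(1, max(1e-6, u))
    stp_params(U = u, f_inc = 0, tau_facil = tau_facil, tau_rec = tau_rec)
  }
}

#' Homogeneous Poisson spike train
#'
#' @param rate_hz Mean rate, Hz (>= 0).
#' @param duration_ms Train duration, ms.
#' @param seed Optional integer seed.
#' @return Sorted spike times in ms (possibly empty).
#' @export
poisson_train <- function(rate_hz, duration_ms, seed = NULL) {
  if (rate_hz < 0) stop("rate must be non-negative")
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
    set.seed(as.integer(seed))
  }
  if (rate_hz == 0) return(numeric(0))
  n <- stats::rpois(1, rate_hz * duration_ms / 1000)
  sort(stats::runif(n, 0, duration_ms))
}
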