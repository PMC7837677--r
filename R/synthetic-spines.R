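#' Noise model for synthetic fluorescence traces
#'
#' Describes the baseline noise and success-transient amplitude statistics used
#' by [generate_linescan_trace()]. Successful release events draw their peak
#' amplitude from a lognormal distribution with the given mean and coefficient
#' of variation; the baseline carries i.i.d. Gaussian noise. The default
#' amplitude-to-noise ratio is 8, comfortably above the 2-SD success criterion
#' used by the trial classifier.
#'
#' @param baseline_sd Baseline noise SD, fluorescence units (> 0).
#' @param success_amplitude_mean Mean peak amplitude of a successful transient,
#'   fluorescence units.
#' @param success_amplitude_cv Coefficient of variation of success amplitudes
#'   (0 switches amplitude variability off).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(baseline_sd = 1,
                        success_amplitude_mean = 8,
                        success_amplitude_cv = 0.2) {
  if (baseline_sd <= 0) stop("baseline_sd must be positive")
  if (success_amplitude_mean < 0) stop("success_amplitude_mean must be >= 0")
  if (success_amplitude_cv < 0) stop("success_amplitude_cv must be >= 0")
  structure(list(baseline_sd = baseline_sd,
                 success_amplitude_mean = success_amplitude_mean,
                 success_amplitude_cv = success_amplitude_cv),
            class = "noise_model")
}

#' Fluorescence trace container
#'
#' A regularly sampled fluorescence time series with its stimulus times and
#' optional ground-truth metadata (used throughout by the synthetic generators
#' and the analysis functions).
#'
#' @param time_ms Time grid, ms.
#' @param value Fluorescence values (arbitrary units, or dF/F0 for derived
#'   traces).
#' @param stim_times Stimulus onset times, ms.
#' @param unit Label for the y axis (e.g. `"dG/R"`, `"dF/F0"`).
#' @param meta Optional named list of ground-truth/bookkeeping fields.
#' @return A list of class `fluor_trace`.
#' @export
fluor_trace <- function(time_ms, value, stim_times = numeric(0),
                        unit = "a.u.", meta = list()) {
  stopifnot(length(time_ms) == length(value))
  structure(list(time_ms = as.numeric(time_ms), value = as.numeric(value),
                 stim_times = as.numeric(stim_times), unit = unit,
                 meta = meta),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("fluor_trace: %d samples, %.0f-%.0f ms, %d stimuli [%s]\n",
              length(x$time_ms), min(x$time_ms), max(x$time_ms),
              length(x$stim_times), x$unit))
  invisible(x)
}

#' Per-spine release-probability trend used by the generators
#'
#' Distance-dependent first-pulse release probability `P1(x) = intercept +
#' slope * x` and the paired-pulse ratio profile `PPR(x)` giving
#' `P2(x) = P1(x) * PPR(x)`; both probabilities are clipped to [0.01, 0.99]
#' when used for trial sampling.
#'
#' @keywords internal
.trend_p1 <- function(x, slope, intercept) intercept + slope * x

#' Generate a synthetic optical-quantal-analysis spine dataset
#'
#' Draws `n_spines` spine locations over `distance_range` (uniform path
#' distance to the soma) and, for each, a ground-truth first-pulse release
#' probability from a linear distance trend (default `P1(x) = 0.18 + 0.0012 x`)
#' together with a second-pulse probability `P2(x) = P1(x) * (3.31 - 0.0074 x)`
#' from the paired-pulse-ratio trend. Each spine then receives
#' `trials_per_spine` paired Bernoulli trials: the first-pulse outcome drawn
#' with `true_P1` and the second-pulse outcome drawn independently with
#' `true_P2` (the marginal probabilities; an optional `rho` induces positive
#' or negative correlation between the two pulses via a Gaussian copula).
#'
#' Spines also carry branch coordinates (origin distance, branch length) and a
#' local spine density so branch-level statistics can be exercised.
#'
#' @param n_spines Number of spines (> 0).
#' @param trials_per_spine Paired-pulse trials per spine (> 0).
#' @param trend_slope Slope of the P1 distance trend, per micrometre.
#' @param trend_intercept Intercept of the P1 trend (probability).
#' @param distance_range Length-2 numeric, micrometres, within (0, 400].
#' @param ppr_trend Length-2 numeric `c(slope, intercept)` of the PPR distance
#'   trend (default `c(-0.0074, 3.31)`).
#' @param rho Correlation between pulse-1 and pulse-2 latent draws (default 0,
#'   i.e. independent pulses).
#' @param seed Integer seed; the dataset is bit-reproducible given the seed.
#' @return A list of class `spine_dataset` with elements `spines` (data frame:
#'   `spine_id, distance_um, branch_origin_um, branch_length_um, true_P1,
#'   true_P2, spine_density_per10um`) and `trials` (long data frame:
#'   `spine_id, trial_idx, s1, s2`).
#' @examples
#' ds <- generate_spine_dataset(n_spines = 10, trials_per_spine = 20, seed = 1)
#' head(ds$trials)
#' @export
generate_spine_dataset <- function(n_spines,
                                   trials_per_spine,
                                   trend_slope = 0.0012,
                                   trend_intercept = 0.18,
                                   distance_range = c(40, 350),
                                   ppr_trend = c(-0.0074, 3.31),
                                   rho = 0,
                                   seed = 1L) {
  if (n_spines <= 0 || trials_per_spine <= 0)
    stop("n_spines and trials_per_spine must be positive")
  if (length(distance_range) != 2 || diff(distance_range) <= 0)
    stop("distance_range must be an increasing length-2 interval")
  if (distance_range[1] <= 0 || distance_range[2] > 400)
    stop("distance_range must lie within (0, 400] um")
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")

  old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
  set.seed(as.integer(seed))

  x <- stats::runif(n_spines, distance_range[1], distance_range[2])
  p1 <- pmin(0.99, pmax(0.01, .trend_p1(x, trend_slope, trend_intercept)))
  ppr <- ppr_trend[2] + ppr_trend[1] * x
  p2 <- pmin(0.99, pmax(0.01, p1 * ppr))

  branch_length <- stats::runif(n_spines, 80, 200)
  branch_origin <- stats::runif(n_spines, 0, 1) * branch_length
  density <- pmax(1, stats::rpois(n_spines, lambda = 8 + 0.02 * x))

  spines <- data.frame(
    spine_id = sprintf("sp%03d", seq_len(n_spines)),
    distance_um = x,
    branch_origin_um = branch_origin,
    branch_length_um = branch_length,
    true_P1 = p1,
    true_P2 = p2,
    spine_density_per10um = density)

  ntr <- as.integer(trials_per_spine)
  # Gaussian copula for optional pulse-1/pulse-2 correlation; rho = 0 reduces
  # to independent Bernoulli draws with the marginal probabilities.
  z1 <- matrix(stats::rnorm(n_spines * ntr), n_spines, ntr)
  z2r <- matrix(stats::rnorm(n_spines * ntr), n_spines, ntr)
  z2 <- rho * z1 + sqrt(1 - rho^2) * z2r
  s1 <- z1 < stats::qnorm(p1)          # recycled by column: p1 per row
  s2 <- z2 < stats::qnorm(p2)

  trials <- data.frame(
    spine_id = rep(spines$spine_id, times = ntr),
    trial_idx = rep(seq_len(ntr), each = n_spines),
    s1 = as.integer(s1),
    s2 = as.integer(s2))
  trials <- trials[order(trials$spine_id, trials$trial_idx), ]
  rownames(trials) <- NULL

  structure(list(spines = spines, trials = trials), class = "spine_dataset")
}

#' @export
print.spine_dataset <- function(x, ...) {
  cat(sprintf("spine_dataset: %d spines x %d trials\n",
              nrow(x$spines), nrow(x$trials) / nrow(x$spines)))
  invisible(x)
}

#' Generate a synthetic linescan Ca2+ trace for one paired-pulse trial
#'
#' Emulates the width-integrated linescan dG/R profile of a dendritic spine
#' during a paired-pulse trial: Gaussian baseline noise plus, for each
#' successful pulse, a transient with a fast rise and mono-exponential decay
#' whose peak amplitude is drawn from the noise model's lognormal distribution.
#'
#' @param outcome Length-2 integer `c(s1, s2)` of success flags.
#' @param noise A [noise_model()].
#' @param stim_times Length-2 stimulus times, ms (default 100 and 150, i.e.
#'   the 50 ms paired-pulse interval).
#' @param kinetics Length-2 `c(rise_ms, decay_ms)` of the transient.
#' @param duration Trace duration, ms.
#' @param rate_hz Sampling rate (default 500 Hz, the linescan rate).
#' @param seed Optional integer seed.
#' @return A [fluor_trace()] with `meta$outcome` holding the ground truth and
#'   `meta$amplitudes` the drawn per-pulse peak amplitudes.
#' @export
generate_linescan_trace <- function(outcome,
                                    noise = noise_model(),
                                    stim_times = c(100, 150),
                                    kinetics = c(2, 40),
                                    duration = 500,
                                    rate_hz = 500,
                                    seed = NULL) {
  outcome <- as.integer(outcome)
  stopifnot(length(outcome) == 2, all(outcome %in% c(0L, 1L)))
  if (any(stim_times < 0) || any(stim_times > duration))
    stop("stimulus times must lie within the trace window")
  if (!is.null(seed)) {
    old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
    set.seed(as.integer(seed))
  }
  dt <- 1000 / rate_hz
  t <- seq(0, duration, by = dt)
  v <- stats::rnorm(length(t), 0, noise$baseline_sd)

  amps <- numeric(2)
  for (k in 1:2) {
    if (outcome[k] == 1L) {
      a <- noise$success_amplitude_mean
      if (noise$success_amplitude_cv > 0 && a > 0) {
        sdlog <- sqrt(log(1 + noise$success_amplitude_cv^2))
        a <- stats::rlnorm(1, meanlog = log(a) - sdlog^2 / 2, sdlog = sdlog)
      }
      amps[k] <- a
      v <- v + a * .alpha_kernel(t - stim_times[k], kinetics[1], kinetics[2])
    }
  }
  fluor_trace(t, v, stim_times, unit = "dG/R",
              meta = list(outcome = outcome, amplitudes = amps,
                          kinetics = kinetics, noise = noise))
}

# difference-of-exponentials transient normalised to unit peak; zero before 0
.alpha_kernel <- function(t, rise, decay) {
  stopifnot(rise > 0, decay > rise)
  tp <- (rise * decay / (decay - rise)) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- ifelse(t >= 0, (exp(-t / decay) - exp(-t / rise)) / peak, 0)
  out
}

#' Write / read the spine trial table as CSV
#'
#' The on-disk schema is `spine_id, distance_um, branch_origin_um,
#' branch_length_um, trial_idx, s1, s2` (one row per trial, spine metadata
#' repeated), matching the layout the quantal-analysis functions read.
#'
#' @param dataset A `spine_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trials_csv <- function(dataset, path) {
  m <- merge(dataset$trials,
             dataset$spines[, c("spine_id", "distance_um", "branch_origin_um",
                                "branch_length_um")],
             by = "spine_id")
  m <- m[order(m$spine_id, m$trial_idx),
         c("spine_id", "distance_um", "branch_origin_um", "branch_length_um",
           "trial_idx", "s1", "s2")]
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  m <- utils::read.csv(path)
  spines <- unique(m[, c("spine_id", "distance_um", "branch_origin_um",
                         "branch_length_um")])
  rownames(spines) <- NULL
  trials <- m[, c("spine_id", "trial_idx", "s1", "s2")]
  structure(list(spines = spines, trials = trials), class = "spine_dataset")
}

#' Read a per-spine summary table (published source-data layout)
#'
#' Reads a CSV of per-synapse summary readouts with columns `spine_id,
#' distance_um, P1, P2, PPR` (additional columns are kept), the layout used by
#' published per-synapse source-data spreadsheets.
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_spine_summary <- function(path) {
  d <- utils::read.csv(path)
  need <- c("distance_um", "P1")
  if (!all(need %in% names(d)))
    stop("summary table must contain at least columns distance_um and P1")
  d
}
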