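#' Generate synthetic iGluSnFR bouton traces with spillover mixing
#'
#' Emulates extracellular glutamate-sensor recordings at axonal boutons.
#' Because glutamate can travel ~2 micrometres from its release site and the
#' local synapse density is high, each recorded bouton reports the summed
#' release of `n_neighbours` synapses (see [spillover_config()]); single-trial
#' release failures therefore become undetectable as the neighbourhood grows
#' (the probability that all neighbours fail is `(1 - Pr)^n`).
#'
#' Each trace is the sum over neighbouring synapses of their stochastic
#' Bernoulli releases convolved with a mono-exponential sensor kernel
#' (default decay 40 ms, instantaneous rise), scaled so the expected
#' first-pulse response is `peak_dff` in dF/F0 units, converted to raw
#' fluorescence around a baseline `F0`, with Gaussian noise added.
#'
#' @param n_boutons Number of boutons (> 0).
#' @param distance_range Length-2, micrometres from the s. pyramidale border.
#' @param ppr_profile `c(slope, intercept)` of the per-bouton paired-pulse
#'   amplitude-ratio trend vs distance. The default gives PPR ~1.8 at 40
#'   micrometres falling to ~1.2 at 350, mean ~1.49 over the range.
#' @param slope_profile `c(slope, intercept)` of the five-pulse peak-slope
#'   trend vs distance (dF/F0 per stimulus); used by `mode = "burst5"`.
#' @param spill A [spillover_config()]; `n_neighbours` synapses contribute.
#'   Use `spillover_config(0, 0)`-like settings only with
#'   `spillover = FALSE`.
#' @param mode `"paired"` (2 stimuli, 50 ms apart), `"burst5"` (5 stimuli at
#'   20 Hz), or `"frame_subsampled"` (burst5 decimated to `frame_ms` frames).
#' @param p1 Per-synapse first-pulse release probability (default 0.36).
#' @param peak_dff Expected first-pulse response amplitude, dF/F0 (default
#'   0.37, i.e. 37%).
#' @param noise_sd Gaussian noise SD on the dF/F0 scale (default 0.02).
#' @param tau_sensor Sensor decay constant, ms (default 40).
#' @param frame_ms Frame interval for `"frame_subsampled"` (default 20).
#' @param f0 Baseline fluorescence level of the raw trace (default 100).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return List of [fluor_trace()] objects (raw fluorescence, `unit = "F"`),
#'   each with ground truth in `meta`: `distance_um`, `true_ppr`,
#'   `true_peak_slope`, `n_released` (per pulse), `true_amplitudes`.
#' @export
generate_iglu_dataset <- function(n_boutons,
                                  distance_range = c(40, 350),
                                  ppr_profile = c(-0.002, 1.88),
                                  slope_profile = c(2e-4, -8e-3),
                                  spill = spillover_config(),
                                  mode = c("paired", "burst5",
                                           "frame_subsampled"),
                                  p1 = 0.36,
                                  peak_dff = 0.37,
                                  noise_sd = 0.02,
                                  tau_sensor = 40,
                                  frame_ms = 20,
                                  f0 = 100,
                                  seed = 1L) {
  mode <- match.arg(mode)
  if (n_boutons <= 0) stop("n_boutons must be positive")
  n_syn <- spill$n_neighbours
  if (n_syn == 0) stop("n_neighbours = 0: spillover generation needs neighbours")
  old <- .Random.seed_exists(); on.exit(old(), add = TRUE)
  set.seed(as.integer(seed))

  n_pulse <- if (mode == "paired") 2L else 5L
  dt_stim <- 50
  t0 <- 200                      # first stimulus; leaves >=150 ms baseline
  stim_times <- t0 + dt_stim * (seq_len(n_pulse) - 1)
  duration <- max(stim_times) + 300
  samp_ms <- if (mode == "frame_subsampled") frame_ms else 2
  t <- seq(0, duration, by = samp_ms)

  x <- stats::runif(n_boutons, distance_range[1], distance_range[2])
  out <- vector("list", n_boutons)
  for (b in seq_len(n_boutons)) {
    ppr_b <- ppr_profile[2] + ppr_profile[1] * x[b]
    slope_b <- slope_profile[2] + slope_profile[1] * x[b]
    # per-pulse per-synapse release probabilities
    if (mode == "paired") {
      p_pulse <- c(p1, min(0.99, p1 * ppr_b))
    } else {
      # burst: expected peak amplitudes follow the per-bouton linear slope
      a_target <- peak_dff + slope_b * (seq_len(n_pulse) - 1)
      p_pulse <- pmin(0.99, pmax(0.01, p1 * a_target / peak_dff))
    }
    q <- peak_dff / (n_syn * p1 * spill$activated_fraction)  # quantal dF/F0
    n_act <- max(1L, round(n_syn * spill$activated_fraction))
    released <- stats::rbinom(n_pulse, n_act, p_pulse)
    dff <- numeric(length(t))
    amps <- q * released
    for (k in seq_len(n_pulse)) {
      dff <- dff + amps[k] * ifelse(t >= stim_times[k],
                                    exp(-(t - stim_times[k]) / tau_sensor), 0)
    }
    dff <- dff + stats::rnorm(length(t), 0, noise_sd)
    out[[b]] <- fluor_trace(t, f0 * (1 + dff), stim_times, unit = "F",
                            meta = list(distance_um = x[b],
                                        true_ppr = ppr_b,
                                        true_peak_slope = slope_b,
                                        n_released = released,
                                        true_amplitudes = amps,
                                        tau_sensor = tau_sensor,
                                        F0 = f0, mode = mode))
  }
  out
}
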