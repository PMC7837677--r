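# Shared fixtures, built once per test run.

# a compact cell that still reaches 350 um (fast to discretise and simulate)
small_morph <- function() {
  generate_morphology(trunk_length = 360, n_obliques = 2,
                      oblique_spacing = 60, oblique_length = 80,
                      n_basal = 2, basal_length = 100, node_step = 20)
}

.small_comps_cache <- new.env()
small_comps <- function() {
  if (is.null(.small_comps_cache$c))
    .small_comps_cache$c <- discretise(small_morph(), max_seg_len = 20)
  .small_comps_cache$c
}

# two-node SWC cylinder morphology (soma-less: soma node reused as thin root)
cylinder_morph <- function(length_um, radius_um, step = 25) {
  y <- seq(step, length_um, by = step)
  n <- length(y)
  nodes <- data.frame(
    id = seq_len(n + 1), type = c(1L, rep(4L, n)),
    x = 0, y = c(0, y), z = 0,
    radius = radius_um,
    parent = c(-1L, seq_len(n)))
  structure(list(nodes = nodes), class = "dendrite_morphology")
}

# build an ideal dF/F0 trace of difference-free mono-exponential transients
ideal_glu_trace <- function(amps, stim_times, tau = 40, duration = NULL,
                            dt = 2, f0 = 100, noise_sd = 0) {
  if (is.null(duration)) duration <- max(stim_times) + 300
  t <- seq(0, duration, by = dt)
  dff <- numeric(length(t))
  for (k in seq_along(amps))
    dff <- dff + amps[k] * ifelse(t >= stim_times[k],
                                  exp(-(t - stim_times[k]) / tau), 0)
  if (noise_sd > 0) dff <- dff + stats::rnorm(length(t), 0, noise_sd)
  fluor_trace(t, f0 * (1 + dff), stim_times, unit = "F")
}
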