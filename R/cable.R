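#' Passive and active membrane parameters for the cable model
#'
#' Defaults follow the simulated CA1 cell: axial resistivity 90 ohm cm,
#' specific capacitance 1 uF/cm2, leak conductance 1/28000 S/cm2 (membrane
#' resistivity 28 kOhm cm2) with the leak reversal at the -65 mV holding
#' potential used as rest. The optional spiking mechanism is a standard
#' Hodgkin-Huxley Na/K pair at the soma (optionally extending into the
#' proximal tree via the dendritic densities), with defaults that give
#' graded repetitive firing on strong synaptic drive.
#'
#' @param ra_ohm_cm Axial resistivity, ohm cm.
#' @param cm_uF_cm2 Specific membrane capacitance, uF/cm2.
#' @param g_leak_S_cm2 Leak conductance density, S/cm2.
#' @param e_leak_mV Leak reversal / resting potential, mV.
#' @param active Logical: enable the Na/K spiking mechanism.
#' @param gna_S_cm2,gk_S_cm2 Peak somatic Na/K conductance densities, S/cm2.
#'   The default Na density is axon-initial-segment scale, collapsed into the
#'   soma so the single somatic compartment can regenerate spikes against the
#'   axial load of the dendritic tree; the K density is chosen for graded
#'   repetitive firing (no depolarisation block) across the physiological
#'   input range.
#' @param gna_dend_S_cm2,gk_dend_S_cm2 Dendritic Na/K densities, S/cm2
#'   (default 0: the minimal spiking mechanism is somatic; set these to
#'   explore dendritic excitability).
#' @param ena_mV,ek_mV Na/K reversal potentials, mV.
#' @param active_extent_um Path distance up to which the dendritic Na/K
#'   mechanism is inserted (soma always included when `active`).
#' @param temperature_C Nominal temperature (bookkeeping; rate constants are
#'   not Q10-scaled).
#' @return A list of class `cable_params`.
#' @export
cable_params <- function(ra_ohm_cm = 90, cm_uF_cm2 = 1,
                         g_leak_S_cm2 = 1 / 28000, e_leak_mV = -65,
                         active = FALSE,
                         gna_S_cm2 = 0.75, gk_S_cm2 = 0.10,
                         gna_dend_S_cm2 = 0, gk_dend_S_cm2 = 0,
                         ena_mV = 50, ek_mV = -77,
                         active_extent_um = 400,
                         temperature_C = 34) {
  if (ra_ohm_cm <= 0 || cm_uF_cm2 <= 0) stop("Ra and Cm must be positive")
  if (g_leak_S_cm2 < 0) stop("g_leak must be non-negative")
  structure(list(ra_ohm_cm = ra_ohm_cm, cm_uF_cm2 = cm_uF_cm2,
                 g_leak_S_cm2 = g_leak_S_cm2, e_leak_mV = e_leak_mV,
                 active = active, gna_S_cm2 = gna_S_cm2, gk_S_cm2 = gk_S_cm2,
                 gna_dend_S_cm2 = gna_dend_S_cm2,
                 gk_dend_S_cm2 = gk_dend_S_cm2,
                 ena_mV = ena_mV, ek_mV = ek_mV,
                 active_extent_um = active_extent_um,
                 temperature_C = temperature_C),
            class = "cable_params")
}

#' Discretise a morphology into cable compartments
#'
#' Splits every SWC edge into cylindrical segments of at most `max_seg_len`
#' micrometres (frustum-interpolated radii, so segment membrane areas sum
#' exactly to the analytic frustum areas), computes each segment's membrane
#' area, capacitance, leak and channel conductances, and the axial coupling
#' conductance to its parent from the axial resistivity and the geometry
#' (centre-to-centre, half-segment resistances in series). The soma sphere
#' becomes the root compartment with area `4 pi r^2`.
#'
#' @param morph A `dendrite_morphology`.
#' @param max_seg_len Maximum segment length, micrometres.
#' @param params A [cable_params()].
#' @param spine_factor Dendritic membrane area multiplier accounting for the
#'   spine membrane not represented in the reconstruction (applied to
#'   capacitance and membrane conductances of non-soma compartments, not to
#'   the axial geometry). Default 2, the conventional correction.
#' @return An object of class `cable_compartments`: a data frame with one row
#'   per compartment (`comp, parent, x_um, length_um, radius_um, area_cm2,
#'   g_axial_uS, cm_nF, g_leak_uS, gna_uS, gk_uS`), compartment 1 being the
#'   soma; `params` kept as an attribute.
#' @export
discretise <- function(morph, max_seg_len = 10, params = cable_params(),
                       spine_factor = 2) {
  if (max_seg_len <= 0) stop("max_seg_len must be positive")
  if (spine_factor < 1) stop("spine_factor must be >= 1")
  validate_morphology(morph)
  n <- morph$nodes
  pd <- path_distances(morph)
  root <- which(n$parent == -1L)
  um2cm <- 1e-4

  r_soma <- n$radius[root] * um2cm
  comp <- data.frame(comp = 1L, parent = 0L, type = 1L, x_um = 0,
                     length_um = 2 * n$radius[root],
                     radius_um = n$radius[root],
                     area_cm2 = 4 * pi * r_soma^2,
                     rax_half = r_soma / (pi * r_soma^2))
  node_comp <- integer(nrow(n)); node_comp[root] <- 1L

  idx <- match(n$parent, n$id)
  order_nodes <- order(pd)  # parents before children
  for (i in order_nodes) {
    if (n$parent[i] == -1L) next
    p <- idx[i]
    L <- pd[i] - pd[p]
    if (L <= 0) stop("degenerate zero-length section at node id ", n$id[i])
    nseg <- ceiling(L / max_seg_len)
    f <- seq(0, 1, length.out = nseg + 1)
    rp <- n$radius[p]; rc <- n$radius[i]
    # when leaving the soma sphere, taper from the child's own radius
    if (n$type[p] == 1L) rp <- rc
    parent_comp <- node_comp[p]
    for (j in seq_len(nseg)) {
      r1 <- rp + (rc - rp) * f[j]
      r2 <- rp + (rc - rp) * f[j + 1]
      lj <- L * (f[j + 1] - f[j])
      slant <- sqrt(((r1 - r2) * um2cm)^2 + (lj * um2cm)^2)
      rbar <- (r1 + r2) / 2 * um2cm
      comp_new <- data.frame(
        comp = nrow(comp) + 1L, parent = parent_comp, type = n$type[i],
        x_um = pd[p] + L * (f[j] + f[j + 1]) / 2,
        length_um = lj, radius_um = (r1 + r2) / 2,
        area_cm2 = pi * (r1 + r2) * um2cm * slant,
        rax_half = (lj * um2cm / 2) / (pi * rbar^2))
      comp <- rbind(comp, comp_new)
      parent_comp <- comp_new$comp
    }
    node_comp[i] <- parent_comp
  }

  # axial conductance: half-resistances of the two coupled segments in series
  g_ax <- numeric(nrow(comp))
  for (i in 2:nrow(comp)) {
    rr <- params$ra_ohm_cm * (comp$rax_half[i] + comp$rax_half[comp$parent[i]])
    g_ax[i] <- 1e6 / rr
  }
  comp$g_axial_uS <- g_ax
  marea <- comp$area_cm2 * ifelse(comp$type == 1L, 1, spine_factor)
  comp$cm_nF <- params$cm_uF_cm2 * marea * 1e3
  comp$g_leak_uS <- params$g_leak_S_cm2 * marea * 1e6
  soma <- comp$comp == 1L
  dend_active <- params$active & !soma & comp$x_um <= params$active_extent_um
  comp$gna_uS <- ifelse(params$active & soma, params$gna_S_cm2 * marea * 1e6,
                        ifelse(dend_active,
                               params$gna_dend_S_cm2 * marea * 1e6, 0))
  comp$gk_uS <- ifelse(params$active & soma, params$gk_S_cm2 * marea * 1e6,
                       ifelse(dend_active,
                              params$gk_dend_S_cm2 * marea * 1e6, 0))
  comp$rax_half <- NULL
  attr(comp, "params") <- params
  class(comp) <- c("cable_compartments", "data.frame")
  comp
}

#' Find the compartment nearest a path distance
#'
#' @param comps A `cable_compartments`.
#' @param x_um Target path distance(s), micrometres.
#' @param dendrite_only Exclude the soma compartment (default TRUE).
#' @param types Optional SWC types to restrict the search to (e.g. `4L` for
#'   apical dendrite).
#' @return Integer compartment index (vectorised over `x_um`).
#' @export
comp_at_distance <- function(comps, x_um, dendrite_only = TRUE, types = NULL) {
  cand <- if (dendrite_only) which(comps$comp != 1L) else seq_len(nrow(comps))
  if (!is.null(types)) {
    tc <- intersect(cand, which(comps$type %in% types))
    if (length(tc)) cand <- tc
  }
  vapply(x_um, function(x) {
    if (x > max(comps$x_um[cand]) + 1e-9)
      stop("requested distance ", x, " um is beyond the morphology extent")
    cand[which.min(abs(comps$x_um[cand] - x))]
  }, integer(1))
}

#' Dual-exponential synaptic conductance event
#'
#' An Exp2Syn-style conductance transient
#' `g(t) = w (exp(-t/tau2) - exp(-t/tau1))` starting at `onset`, with rise
#' `tau1` and decay `tau2`. By default `w` is scaled so the conductance peak
#' equals `gmax_uS` (the reference simulator's convention); with
#' `normalise = FALSE` the raw difference-of-exponentials amplitude factor is
#' `gmax_uS` itself.
#'
#' @param comp Target compartment index (or `NA` with `x_um` given).
#' @param onset Event onset, ms, relative to the protocol start.
#' @param gmax_uS Peak conductance, uS.
#' @param tau1,tau2 Rise and decay time constants, ms (`0 < tau1 < tau2`).
#' @param erev_mV Reversal potential, mV (0 for excitatory).
#' @param x_um Optional path distance used to resolve `comp` at simulate time.
#' @param normalise Peak-normalise the transient (default TRUE).
#' @return One-row data frame.
#' @export
conductance_event <- function(comp = NA_integer_, onset, gmax_uS,
                              tau1 = 1, tau2 = 20, erev_mV = 0,
                              x_um = NA_real_, normalise = TRUE) {
  if (!(tau1 > 0 && tau2 > tau1)) stop("need 0 < tau1 < tau2")
  if (gmax_uS < 0) stop("gmax_uS must be non-negative")
  data.frame(comp = comp, onset = onset, gmax_uS = gmax_uS, tau1 = tau1,
             tau2 = tau2, erev_mV = erev_mV, x_um = x_um,
             normalise = normalise)
}

.exp2_peak <- function(tau1, tau2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  exp(-tp / tau2) - exp(-tp / tau1)
}

#' Simulate the compartmental cable model
#'
#' Integrates the branched cable equation with Crank-Nicolson time stepping
#' (unconditionally stable; default dt 0.025 ms) after a 300 ms stabilisation
#' run at rest. Synaptic events, Hodgkin-Huxley channels (when the parameters
#' enable them) and current clamps are supported. Numerical divergence aborts
#' with a diagnostic.
#'
#' @param comps A `cable_compartments` (see [discretise()]).
#' @param events Data frame of [conductance_event()] rows (or `NULL`).
#' @param duration Protocol duration, ms (time runs 0..duration after
#'   stabilisation).
#' @param dt Time step, ms; must satisfy `dt <= tau1/4` for every event.
#' @param stabilise_ms Settling run before the protocol (default 300 ms).
#' @param i_clamp Optional data frame `comp, amp_nA, start, dur` of constant
#'   current injections.
#' @param record Compartment indices to record (default soma).
#' @param record_every Keep every k-th sample (default 1).
#' @return An object of class `voltage_trace`: list with `time_ms`, `vm`
#'   (matrix, one column per recorded compartment), `record`, `final_v`
#'   (voltage of every compartment at the end), `dt`.
#' @export
simulate_cable <- function(comps, events = NULL, duration, dt = 0.025,
                           stabilise_ms = 300, i_clamp = NULL,
                           record = 1L, record_every = 1L) {
  stopifnot(inherits(comps, "cable_compartments"))
  params <- attr(comps, "params")

  if (is.null(events) || nrow(events) == 0) {
    syn <- data.frame(comp = integer(0), tau1 = numeric(0),
                      tau2 = numeric(0), erev = numeric(0))
    ev <- data.frame(syn = integer(0), time = numeric(0), w = numeric(0))
  } else {
    events <- as.data.frame(events)
    need_x <- is.na(events$comp)
    if (any(need_x)) events$comp[need_x] <-
        comp_at_distance(comps, events$x_um[need_x])
    if (any(dt > events$tau1 / 4))
      stop("dt must be <= tau1/4 for every synaptic event")
    key <- paste(events$comp, events$tau1, events$tau2, events$erev_mV,
                 events$normalise)
    syn_id <- match(key, unique(key))
    first <- !duplicated(key)
    syn <- data.frame(comp = events$comp[first], tau1 = events$tau1[first],
                      tau2 = events$tau2[first], erev = events$erev_mV[first],
                      normalise = events$normalise[first])
    w <- ifelse(events$normalise,
                events$gmax_uS / .exp2_peak(events$tau1, events$tau2),
                events$gmax_uS)
    ord <- order(events$onset)
    ev <- data.frame(syn = syn_id[ord], time = events$onset[ord], w = w[ord])
  }
  if (is.null(i_clamp))
    i_clamp <- data.frame(comp = integer(0), amp_nA = numeric(0),
                          start = numeric(0), dur = numeric(0))

  res <- simulate_cable_cpp(
    parent = as.integer(comps$parent) - 1L,
    cm_nF = comps$cm_nF, g_leak_uS = comps$g_leak_uS,
    e_leak = params$e_leak_mV, g_axial_uS = comps$g_axial_uS,
    gna_uS = comps$gna_uS, gk_uS = comps$gk_uS,
    ena = params$ena_mV, ek = params$ek_mV,
    syn_comp = as.integer(syn$comp) - 1L, syn_tau1 = syn$tau1,
    syn_tau2 = syn$tau2, syn_erev = syn$erev,
    ev_syn = as.integer(ev$syn) - 1L, ev_time = ev$time, ev_w = ev$w,
    ic_comp = as.integer(i_clamp$comp) - 1L, ic_amp_nA = i_clamp$amp_nA,
    ic_start = i_clamp$start, ic_dur = i_clamp$dur,
    duration = duration, dt = dt, stabilise = stabilise_ms,
    record_comp = as.integer(record) - 1L,
    record_every = as.integer(record_every))

  structure(list(time_ms = as.numeric(res$time_ms),
                 vm = as.matrix(res$vm), record = as.integer(record),
                 final_v = as.numeric(res$final_v), dt = dt,
                 e_rest = params$e_leak_mV),
            class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("voltage_trace: %d samples x %d compartments, %.1f ms, dt = %g ms\n",
              length(x$time_ms), ncol(x$vm), max(x$time_ms), x$dt))
  invisible(x)
}

#' EPSP amplitude from a somatic voltage trace
#'
#' Peak depolarisation inside `[stim_onset, stim_onset + window]`. With
#' `ref = "onset"` (the default, used for second-pulse amplitudes) the
#' voltage at the stimulus onset is subtracted; with `ref = "rest"` the
#' stabilised pre-protocol resting potential (the first recorded sample,
#' which under active membrane parameters can differ from the leak
#' reversal) is. A detected spike inside the window
#' (peak above `spike_threshold`) flags the measurement as invalid via the
#' `spike` attribute.
#'
#' @param trace A `voltage_trace` (soma in column 1).
#' @param stim_onset Stimulus onset, ms.
#' @param window Search window length, ms.
#' @param ref `"onset"` or `"rest"`.
#' @param spike_threshold mV; peaks above this flag a spike.
#' @return EPSP amplitude in mV with attribute `spike` (logical).
#' @export
epsp_amplitude <- function(trace, stim_onset, window = 50,
                           ref = c("onset", "rest"), spike_threshold = 0) {
  ref <- match.arg(ref)
  t <- trace$time_ms; v <- trace$vm[, 1]
  if (stim_onset + window > max(t) + 1e-9)
    stop("window extends past the end of the trace")
  win <- t >= stim_onset & t <= stim_onset + window
  base <- if (ref == "rest") v[1] else
    v[max(1, which(t >= stim_onset)[1] - 1)]
  pk <- max(v[win])
  out <- pk - base
  attr(out, "spike") <- pk > spike_threshold
  out
}

#' Detect spikes in a voltage trace
#'
#' Upward threshold crossings (default 0 mV), merging crossings closer than
#' a 2 ms refractory interval.
#'
#' @param trace A `voltage_trace` (uses column 1).
#' @param threshold_mV Detection threshold, mV.
#' @param refractory_ms Minimum separation between spikes, ms.
#' @return Numeric vector of spike times, ms.
#' @export
detect_spikes <- function(trace, threshold_mV = 0, refractory_ms = 2) {
  t <- trace$time_ms; v <- trace$vm[, 1]
  up <- which(v[-1] >= threshold_mV & v[-length(v)] < threshold_mV)
  if (!length(up)) return(numeric(0))
  times <- t[up + 1]
  keep <- c(TRUE, diff(times) > refractory_ms)
  times[keep]
}
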