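---
title: "Models and methods behind synaptrend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptrend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptrend)
```

## The scientific question

At CA3-CA1 synapses the probability `Pr` that an afferent spike triggers
glutamate release varies widely between synapses. Optical quantal analysis
(OQA) — scoring postsynaptic Ca²⁺ transients at single dendritic spines as
successes or failures over repeated paired-pulse stimuli — shows that `Pr`
*increases* with the distance of the synapse from the soma, roughly as

```
P1(x) = 0.18 + 0.0012 x          (x in micrometres)
P2(x) = P1(x) * (3.31 - 0.0074 x)
```

so that proximal synapses are unreliable but strongly facilitating, while
distal synapses are reliable with little paired-pulse facilitation. This
package implements (i) the OQA estimators and trend statistics, (ii) the
analysis of iGluSnFR glutamate-sensor fluorescence, and (iii) a stochastic
compartmental simulation asking what this centrifugal `Pr` gradient does to
somatic integration and spiking output. A synthetic-data module generates
every input the analyses assume, so the full pipeline is testable without
imaging data.

## Optical quantal analysis

For each spine, paired-pulse trials (50 ms interval) are reduced to the four
outcome counts (0,0), (0,1), (1,0), (1,1). `estimate_release()` computes

* `P1 = (n10 + n11)/N` — the release probability `Pr`,
* `P2 = (n01 + n11)/N` — the marginal second-pulse probability,
* `P2* = n01/(n00 + n01)` — the second-pulse probability restricted to
  first-pulse failures, robust to indicator saturation by a first response,
* `PPR = P2/P1` and `PPR* = P2*/P1`.

Ratios are flagged `NA` when undefined (`P1 = 0`, or no first-pulse failures
for `P2*`) rather than silently zeroed; the experimental convention is to
exclude such synapses.

**Trial classification.** `classify_trial()` scores a pulse as a success
when its amplitude exceeds the reference level by more than `k_sd = 2`
standard deviations of the failure noise. Two conventions deserve comment:

* *Statistic.* The default amplitude statistic is the **mean of the trace
  over the response window** (5–45 ms post-stimulus), compared against 2 SD
  of the raw noise. A window-maximum statistic is also provided
  (`statistic = "peak"`), but a maximum over ~20 samples at a 2 SD threshold
  carries an irreducible multiple-comparison false-positive rate of several
  percent, which is incompatible with the clean success/failure separation
  the method relies on. The windowed mean has ~4.5-fold smaller sampling
  noise than a single sample, so the 2 SD criterion on raw noise separates
  8-SD-amplitude transients essentially without error.
* *Second-pulse reference.* The second pulse is referenced to the 10 ms
  immediately before its own stimulus, so a second response must rise above
  the decaying tail of the first response, matching the requirement that a
  second response be visible *over* the first.

`classify_spine_trials()` adds the failure-SD refinement: after a first pass
against the baseline SD, the noise SD is re-estimated from the response
windows of first-pulse failure trials and classification re-run once. A
single refinement pass keeps the procedure deterministic.

**Trend statistics.** `regress_trend()` is ordinary least squares with the
two-sided t-test on the slope and Pearson's r. In this specimen-averaged
design the slope p-value, not r, carries the inference: the large
synapse-to-synapse variability around the trend is biology, and
`bin_and_pool()` demonstrates this by averaging `Pr` within 25 µm distance
bins — the same dataset then shows a much higher Pearson's r while the
fitted slope is unchanged. Pair statistics (`pairwise_branch_difference()`,
with the symmetric pair-mean denominator), `relative_branch_position()` and
the closed-interval `spine_density()` window complete the per-figure
statistics. Paired condition comparisons offer both the paired t-test and
the Wilcoxon signed-rank test behind a user flag; the package does not
automate normality-based test selection.

## Glutamate-sensor (iGluSnFR) analysis

Fluorescence is normalised as `dF/F0` with `F0` averaged over ~150 ms before
the first stimulus. Because released glutamate travels ~2 µm and the CA1
neuropil packs ~2 synapses per µm³, a sensor pixel integrates >60 synapses
within its ~33 µm³ neighbourhood (`spillover_config()` does this
arithmetic). Single-trial failures are therefore invisible —
`(1 - 0.36)^67 < 1e-12` — and the signal is useful for amplitude ratios, not
direct `Pr` counting.

`paired_pulse_ratio_glu()` measures `A1` as the windowed peak after pulse 1
and `A2` as the pulse-2 peak after subtracting the extrapolated
mono-exponential decay of response 1 (decay fitted between the first peak
and the second stimulus onset). The ratio is oriented second/first so
facilitation gives PPR > 1, consistent with the OQA `P2/P1`.

`fit_burst5()` handles 20 Hz five-pulse bursts recorded at low frame rates:
the decay constant τ is fitted first on the tail after the fifth pulse, then
the five amplitudes follow by linear least squares with τ fixed, each
component active from its stimulus onset. The burst facilitation indicator
is the OLS slope of the five fitted amplitudes against stimulus index
(`peak_slope`), computed on the reconstructed amplitudes rather than the raw
frame samples. On noiseless bursts the fit recovers amplitudes and τ to well
under 1%, and within 5% from 20 ms frame-subsampled traces.

## The compartmental cable model

`discretise()` converts an SWC morphology into cylindrical segments (≤ 10 µm
by default) with frustum-exact membrane areas; axial conductances couple
segment centres through half-segment resistances. The solver
(`simulate_cable()`, C++ backend) integrates the branched cable equation
with Crank–Nicolson time stepping and Hines elimination — one up-sweep and
one down-sweep per step — so each step is O(compartments) and
unconditionally stable. Synaptic events are dual-exponential (Exp2Syn-style)
conductances, rise 1 ms and decay 20 ms, reversal 0 mV, held as two exactly
decaying state variables per synapse; by default the transient is
peak-normalised so its maximum equals `Gm` (the raw difference-of-exponentials
amplitude convention is available via `normalise = FALSE`). Every protocol
starts from a 300 ms stabilisation run.

Numerical choices and their checks:

* fixed `dt = 0.025 ms` (a fixed step replaces adaptive stepping; halving
  `dt` changes EPSP peaks by < 0.5%, and `dt ≤ tau1/4` is enforced);
* steady-state attenuation on a 4-space-constant cylinder matches the sealed
  cable solution `cosh((L - x)/λ)/cosh(L/λ)` to better than 1%;
* a resting cell holds its potential to < 1 µV over hundreds of ms;
* divergence (non-finite voltage) aborts with a diagnostic rather than
  returning garbage.

Passive parameters follow the reference simulations: `Ra = 90 Ω·cm`,
`Cm = 1 µF/cm²` (the standard biological value), leak 1/28000 S/cm² with
`E_leak = −65 mV` (the whole-cell holding potential used as rest), nominal
34 °C. A `spine_factor` of 2 doubles dendritic
membrane (capacitance and conductances, not axial geometry) to account for
spines absent from the reconstruction.

**Spiking mechanism.** The optional active mechanism is a classic
Hodgkin–Huxley Na/K pair. A single somatic compartment cannot regenerate
spikes against the ~20 µS axial load of the dendritic tree at textbook
densities, so the default somatic Na density (0.75 S/cm²) is the standard
shortcut of collapsing the axon initial segment into the soma; the K density
(0.10 S/cm²) was chosen so firing is graded across the physiological input
range instead of entering depolarisation block. The default cell is silent
at rest and fires overshooting spikes on strong input. Dendritic Na/K
densities are exposed but default to zero (see *Limitations*).

## The stochastic synapse population

`place_synapses()` scatters 50 synapses over the apical tree at path
distances 40–350 µm, uniformly or with a linearly increasing density
("density trend"). The published density regression values are not
available, so the trend-mode default doubles the placement density from 40
to 350 µm — a choice made once for plausibility; the source study reports that the
density trend itself had little effect on the simulated EPSPs. Per synapse:

* `P1`, `P2` from the distance regressions (or 0.36 / 0.77 in the uniform
  condition);
* peak conductance `Gm = A (0.51 + 0.002 x)`, the centrifugal synaptic
  conductance scaling;
* with `rescale_mean = TRUE`, `P1` and `P2` are scaled multiplicatively so
  the realised population mean `P1` is exactly 0.36. The literal trend
  formula averages ≈ 0.414 over uniform placement, while the reference
  simulations kept the mean at 0.36 to match overall input efficacy; both
  behaviours are exposed, and condition comparisons use the rescaled form.

Release is Bernoulli per synapse and pulse, with the second pulse drawn
independently at its marginal `P2` (only marginal probabilities are
specified by the data; the near-identity of `P2` and `P2*` there is
consistent with independence). A correlation knob exists in the spine-data
generator for sensitivity analyses.

**Short-term plasticity.** `stp_evolve()` implements a facilitation/
depression recursion of the Tsodyks–Markram type: utilisation `u` rests at
`U`, release uses `u·R`, resources deplete by the utilised fraction and
recover with `tau_rec`, and `u` is incremented after each spike and relaxes
with `tau_facil`. The per-spike probability is normalised by `U` so an
isolated spike releases with exactly the synapse's base probability.
Defaults (`U = 0.2`, `f_inc = 0.25`, `tau_facil = 100 ms`,
`tau_rec = 60 ms`) express the facilitation/depression transient within the
first 2–4 discharges and converge to a frequency-dependent steady state
within 4 spikes of a 20 Hz train. Because the source of the exact published
STP parameters is not reproduced here, `stp_calibrate_ppr()` instead
calibrates the recursion analytically so its two-spike, 50 ms prediction
equals a target ratio — either the synapse's `P2/P1` field (paired
consistency) or a burst-specific target (below).

## The in-silico experiments

All protocols share seed discipline: a master seed derives per-run placement
and release seeds, identical across compared conditions, so synapse
positions and the uniform variates behind every Bernoulli draw are matched
run-by-run; paired tests are valid by construction and every number is
bit-reproducible.

* **Paired pulse** (`run_paired_pulse()`): two synchronous volleys 50 ms
  apart at the subthreshold scale; 100 runs per condition with fresh
  placement each run. EPSP1 is peak-minus-rest; EPSP2 is peak minus the
  voltage at its own onset (the absolute convention is available through
  `epsp_amplitude(ref = "rest")`). Runs with spikes are flagged and
  excluded.
* **Five-pulse burst** (`run_burst5()`): 20 Hz bursts with the STP engine
  at every synapse; the transfer metric is the time-integral of somatic
  depolarisation over the burst window (mV·ms), a definition chosen here
  (peak-based summaries can be built from the per-run EPSPs). The default
  burst mode calibrates each synapse's STP to the *five-pulse slope trend* —
  burst facilitation increasing with distance, as the glutamate-imaging
  burst data show — with the uniform condition receiving the population
  mean slope so average burst drive is matched. Calibrating bursts to the
  *paired* PPR trend instead (available as `burst_mode =
  "paired_consistency"`) makes distal synapses the least facilitating and
  reverses the condition contrast; the paired regression and the burst
  slope trend are different datasets with opposite distance gradients, and
  the burst experiment follows the burst data.
* **Poisson drive** (`run_io_curve()`): independent homogeneous Poisson
  trains per synapse at the spiking scale, 1–2 s per run, with or without
  STP; output rate from somatic spike detection.

**Conductance scales.** The reference simulations used `A = 0.002 µS`
(subthreshold) and `0.06 µS` (spiking) on a reconstructed cell whose dense
resting conductances make it far leakier than any passive model. On the
passive synthetic cell those values drive ~30 mV compound EPSPs — deep
driving-force saturation that inverts the paired-pulse ratio. The
synthetic-cell defaults are therefore calibrated to the *operating point* of
the reference simulations: `A = 1e-4 µS` puts the mean uniform-condition
EPSP at ~2.6 mV (reference: 2.90 mV), and `A = 1e-3 µS` keeps the
input–output curve graded across 5–100 Hz per-axon input. The reference
values remain appropriate for imported reconstructions with active
membranes.

## The synthetic-data generators

`generate_spine_dataset()` draws spine distances uniformly over 40–350 µm
and paired Bernoulli trials from the ground-truth trends (67 spines × 20
trials is the study-sized default used in tests). `generate_linescan_trace()`
emulates 500 Hz linescan dG/R profiles: Gaussian baseline noise plus
difference-of-exponential transients (rise 2 ms, decay 40 ms) whose success
amplitudes are lognormal with a configurable CV — the true amplitude
distribution of Ca²⁺ successes is not known, so the CV is a knob, not a
claim. `generate_iglu_dataset()` sums stochastic releases of the ~67-synapse
spillover neighbourhood under a mono-exponential sensor kernel (τ = 40 ms,
chosen to resemble published transients), at 500 Hz or decimated to 20 ms
frames; per-bouton paired-pulse ratios fall with distance (defaults give a
population mean ≈ 1.5) while five-pulse peak slopes rise with distance.
`generate_morphology()` builds a CA1-like SWC tree — spherical soma,
3→2 µm tapering apical trunk (500 µm), twelve 220 µm obliques, eight 250 µm
basal dendrites — with CA1-realistic total membrane (~19,000 µm² before the
spine correction) and input resistance (~40 MΩ with the spine factor).

What the generators do **not** emulate: indicator saturation and buffering,
photobleaching, the microscope point-spread function, electrode drift, and
any correlation structure between neighbouring synapses' release beyond the
distance trends. Passing tests therefore demonstrate the correctness of the
estimators and solvers under the stated statistical model of the data, not
robustness to every artefact of real imaging.

## Known limitations

* **Passive dendrites.** The reference model carries a full complement of
  active dendritic conductances; this package substitutes a passive tree
  with an optional minimal somatic spiking mechanism, and dendritic
  regenerative events are out of scope. The consequence is quantitative:
  with `Gm ∝ (0.51 + 0.002x)` the per-synapse somatic efficacy of the
  passive cell rises only ~1.6-fold over 40–350 µm, which caps the
  trend-vs-uniform first-EPSP advantage at ~+4% under linear summation;
  measured values are ~+2% (direction as reported, magnitude well below the
  ~13% obtained with the active reconstruction), and the spiking advantage
  of the gradient does not grow with input rate here. The paired-pulse-ratio
  reduction (~24% vs ~20% reported) and the burst-transfer gain (~+5% vs
  ~15%) are reproduced.
* **Simplified spiking.** Classic HH kinetics without Q10 scaling,
  adaptation, or the reference cell's K-channel diversity; input–output
  rates are meaningful relatively, not absolutely.
* **No amplitude-based quantal decomposition.** Trials are scored
  success/failure only, as in the source method.

## Problem sizes used in the automated checks

The test-suite and the acceptance script use study-sized statistical
problems (67 spines × 20 trials, 33 boutons, 200 replicate datasets) and
simulation sizes chosen for a laptop-scale run: 50–100 paired-pulse runs per
condition, 40 burst runs, and 12–16 Poisson runs per input rate at 1 s per
run. Increasing `n_runs` tightens the Monte-Carlo error of the condition
contrasts without changing their means.
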