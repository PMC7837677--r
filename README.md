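# synaptrend

Quantal analysis, glutamate-imaging analysis and stochastic dendritic
integration for the distance dependence of synaptic release probability in
CA1 pyramidal cells.

## The problem

At CA3-CA1 synapses the release probability Pr — the chance that one
presynaptic spike releases glutamate — varies enormously between synapses.
Optical quantal analysis (scoring Ca²⁺ transients in single dendritic
spines as successes or failures over repeated paired-pulse stimuli) shows
that Pr rises with the synapse's path distance x from the soma while the
paired-pulse ratio falls:

    P1(x)  = 0.18 + 0.0012 x                      (release probability)
    P2(x)  = (0.18 + 0.0012 x)(3.31 − 0.0074 x)   (second-pulse probability)
    PPR(x) = P2/P1 = 3.31 − 0.0074 x

so proximal synapses are unreliable but strongly facilitating, distal ones
reliable with little facilitation. This package is for physiologists and
modellers who want to (1) estimate these quantities from success/failure
trial tables or raw fluorescence traces, (2) analyse iGluSnFR
glutamate-sensor recordings (dF/F₀, paired-pulse amplitude ratios,
five-pulse burst fits on slow frame scans), and (3) simulate what the Pr
gradient does to somatic EPSPs and spiking output, using a branched
compartmental cable model with stochastic Bernoulli synapses and a
configurable short-term-plasticity engine. A synthetic-data module
generates spine trial datasets, noisy linescan traces, spillover-mixed
glutamate signals and SWC morphologies, so the entire pipeline runs and is
tested without any imaging data.

The core estimators, from the four paired-outcome counts
(0,0), (0,1), (1,0), (1,1) of N trials:

    P1  = (n10 + n11) / N         PPR  = P2 / P1
    P2  = (n01 + n11) / N         PPR* = P2* / P1
    P2* = n01 / (n00 + n01)

## Worked example

```r
library(synaptrend)

# a study-sized synthetic OQA dataset: 67 spines x 20 paired-pulse trials
ds  <- generate_spine_dataset(n_spines = 67, trials_per_spine = 20, seed = 1)
est <- estimate_dataset(ds)
head(est[, c("spine_id", "distance_um", "P1", "P2", "PPR")], 3)
#>   spine_id distance_um   P1   P2  PPR
#> 1    sp001         122 0.35 0.70 2.00
#> 2    sp002         155 0.20 0.75 3.75
#> 3    sp003         218 0.50 0.75 1.50

regress_trend(est$distance_um, est$P1)
#> trend_regression: slope = 0.000977 (95% CI 0.000642..0.00131), r = 0.586, p = 1.88e-07, n = 67

bin_and_pool(est$distance_um, est$P1, bin_width = 25)$regression
#> trend_regression: slope = 0.000955 (95% CI 0.000613..0.0013), r = 0.880, p = 7.21e-05, n = 13

spillover_config()
#> spillover_config: 2.0 syn/um^3 within 2.0 um -> 33.5 um^3, 67 neighbours (100% activated)
```

The fitted slope recovers the generating trend (0.0012 per µm inside the
95% CI) with a highly significant non-zero-slope test; pooling Pr into
25 µm bins raises Pearson's r from 0.59 to 0.88 while describing the same
dataset — the motivation for judging the trend by its slope p-value rather
than by r. The spillover arithmetic shows why a glutamate sensor pixel
reports >60 synapses: failures are invisible and only amplitude ratios are
interpretable.

The simulation side runs the same way:

```r
cfg <- experiment_config(conditions = c("uniform", "pr_trend"),
                         n_runs = 100, master_seed = 1)
pp  <- run_paired_pulse(cfg)     # ~1 min; bit-reproducible given the seed
summarise_protocol(pp)
```

which reports, per condition, mean EPSP amplitudes, paired-pulse ratios,
percentage differences and paired p-values (with the distance trend and the
population mean Pr fixed at 0.36, the trend condition raises the first
EPSP slightly and lowers the PPR by ~24% on the passive synthetic cell).

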