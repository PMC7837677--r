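Package: synaptrend
Title: Release-Probability Trends Along CA1 Dendrites: Quantal Analysis and
    Stochastic Dendritic Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how synaptic release probability (Pr) varies
    with distance along the apical dendrites of CA1 pyramidal cells and what
    that gradient does to dendritic integration. Implements optical quantal
    analysis estimators for paired-pulse success/failure trials (P1, P2, P2*,
    paired-pulse ratios) with distance-trend regression and binning statistics;
    analysis of iGluSnFR glutamate-sensor fluorescence (dF/F0 normalisation,
    paired-pulse amplitude ratios, five-pulse overlapping-exponential burst
    fits); a branched compartmental cable solver with passive membrane and a
    minimal Hodgkin-Huxley spiking mechanism; a stochastic Bernoulli-release
    synapse population with distance-dependent Pr, conductance scaling and a
    configurable short-term-plasticity engine; and in-silico experiment
    drivers (paired-pulse, five-pulse burst, Poisson-drive input-output
    curves). A synthetic-data module generates spine trial datasets,
    noisy fluorescence traces, spillover-mixed glutamate signals and SWC
    morphologies so the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
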