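Package: dentatenet
Title: Large-Scale Dentate Gyrus Spiking Network Simulation and Spike-Train Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based spiking network model of the rat hippocampal
    dentate gyrus at configurable scale. Reduced-compartment granule cells and
    single-compartment basket and mossy cells, topographic probabilistic
    connectivity for the perforant-path, feedforward/feedback inhibitory and
    mossy-cell associational pathways, inhomogeneous Poisson entorhinal drive,
    and a clock-driven integration engine. Includes the population analytics
    used to characterise emergent activity (distance-binned spatio-temporal
    spike correlations, spike-density spectra, inter-spike-interval
    histograms), scripted perturbation experiments, and an
    excitation-inhibition rebalancing procedure for the associational loop.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
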