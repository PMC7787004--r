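Package: burstnet
Title: Conductance-Based Models of Rhythmogenic Spinal Interneuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of rhythm generation in heterogeneous
    populations of Hodgkin-Huxley style spinal interneurons. A subset of
    neurons carries a slowly inactivating persistent sodium current (INaP)
    that supports conditional bursting; neurons are coupled by bidirectional
    electrical synapses (gap junctions) and/or unidirectional excitatory
    chemical (AMPA-like) synapses. The package provides the single-neuron
    biophysics, random network construction, a fixed-step second-order
    Runge-Kutta integrator with spike recording (compiled core), burst
    detection and regime classification for single neurons and population
    rate histograms, and drivers for two-cell experiments, 100-neuron
    population runs, two-parameter coupling sweeps and a gap-junction-block
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
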