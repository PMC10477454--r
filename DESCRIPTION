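Package: stngpe
Title: Simulation and Analysis of the Subthalamo-Pallidal Circuit with
    Topographic Synaptic Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spiking-network model of the subthalamic nucleus (STN) and the
    external globus pallidus (GPe) with somatotopically organized synaptic
    connections. Neurons follow adaptive quadratic integrate-and-fire dynamics
    with conductance-based AMPA, NMDA (magnesium block) and GABA-A synapses and
    delayed spike delivery; cortex and striatum are modeled as Poisson spike
    generators. The package builds intact (N), displaced (D) and skipping (S)
    topographic networks, integrates the stochastic dynamics with the
    Euler-Maruyama scheme, calibrates synaptic conductances against target
    firing rates with a Nelder-Mead simplex, and analyses evoked activity via
    peristimulus time histograms, firing-rate distributions, spatio-temporal
    response maps and a two-site (priming/test) stimulation protocol that
    yields functional-channel-width estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
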