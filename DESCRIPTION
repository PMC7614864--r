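Package: ca3pop
Title: Heterogeneous Populations of Conductance-Based CA3 Pyramidal Neuron
    Models and Complex Spike Bursting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and analyses heterogeneous populations of morphologically
    reduced, conductance-based hippocampal CA3 pyramidal neuron models. Provides
    an own compartmental cable solver (backward-Euler branched-cable solve with
    exponential-Euler Hodgkin-Huxley gating and annulus-resolved calcium
    handling), ten voltage- and calcium-gated channel mechanisms with
    somatodendritic distribution rules, colocalized AMPAR-NMDAR synapses with
    Goldman-Hodgkin-Katz multi-ion currents and magnesium block, the standard
    intrinsic electrophysiological measurement battery (input resistance, sag,
    impedance resonance, backpropagating action potential attenuation, firing
    measurements), multi-parametric multi-objective stochastic search with
    rejection against electrophysiological bounds, intrinsically-bursting
    versus regular-spiking classification, complex-spike-burst induction and
    scoring under somatic, dendritic and synaptic protocols, and virtual
    knockout analyses of channel and receptor contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
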