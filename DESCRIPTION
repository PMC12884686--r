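Package: mecgamma
Title: Theta-Nested Gamma Oscillations in a Medial Entorhinal Cortex E-I-I
    Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based simulation and spectral analysis of
    theta-nested gamma oscillations in a medial entorhinal cortex network of
    100 heterogeneously driven fast-spiking PV+ interneurons (Hodgkin-Huxley
    type, chemical GABA_A and gap-junction coupling) and 400 mutually
    unconnected stellate cells with Ornstein-Uhlenbeck conductance noise.
    Networks are sampled reproducibly from seeds, driven by a rectified 8 Hz
    sinusoidal conductance emulating optogenetic theta stimulation, and read
    out through voltage-clamped cells whose synaptic currents are analysed
    with an analytic Morlet wavelet scalogram pipeline (cycle averaging,
    artifact and quality-control exclusions, peak/total gamma power, Welch
    PSD, spike-phase and interspike-interval histograms). Campaign helpers
    reproduce the transition from interneuron network gamma (ING) to
    pyramidal-interneuron network gamma (PING) as excitatory-to-inhibitory
    conductance increases, and the shunting-inhibition control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
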