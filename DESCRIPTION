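Package: adfsim
Title: Cable-Model Simulation of Myelination and Analog-Digital Synaptic Facilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Multicompartment cable-equation simulator for a layer-5 pyramidal
    neuron with a long myelinated main axon, built to quantify how myelin wrap
    number and internode length set the axonal space constant and the spatial
    extent of depolarization- and hyperpolarization-induced analog-digital
    facilitation (d-ADF, h-ADF) of synaptic transmission. Provides a synthetic
    morphology generator with presynaptic sites on axon collaterals, Hodgkin-
    Huxley style channel kinetics, a double-cable (periaxonal space plus myelin
    sheath) internode model, an implicit tree solver with a steady-state fast
    path, somatic stimulation protocols, presynaptic spike and calcium metrics,
    a power-law release model, and the analysis pipeline for attenuation
    profiles, 37-percent-rule space constants, 105-percent facilitation
    crossings and wrap-number curve fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
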