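Package: spiketom
Title: Spiking Neural Network Model of False-Belief Reasoning from Self-Experience
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A brain-region-structured spiking neural network that learns
    object permanence and visual access from first-person experience and uses
    them, through an inhibitory-control circuit, to pass non-verbal
    false-belief (unexpected transfer) tasks. Provides a conductance-based
    leaky integrate-and-fire simulator, a voltage-driven plasticity training
    scheme combining homeostatic membrane-potential learning, supervised
    last-layer teaching and STDP weight consolidation, a symbolic scenario
    generator standing in for robot vision, and an experiment harness for the
    blindfold, turn-around, control and maturation-ablation protocols.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
SystemRequirements: C++17
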