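Package: glifnet
Title: Design and Simulation of Rate-Coded Spiking Pathways with
    Generalized Integrate-and-Fire Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building rate-coded neural pathways from generalized
    leaky integrate-and-fire (GLIF) neurons with adaptive spike thresholds
    and conductance-based spiking synapses, together with their non-spiking
    leaky-integrator equivalents.  Provides closed-form characterizations
    of steady-state and transient spiking frequency, the implicit spike-time
    threshold equation and its explicit approximation, and time-averaged
    synaptic conductance.  Implements the functional subnetwork approach
    (FSA) for spiking pathways: neuron and synapse parameters are computed
    directly from network-wide activation constants and intended synaptic
    gains, then verified by forward-Euler simulation of single neurons,
    all-to-all population pathways, and a closed-loop muscle stretch-reflex
    demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
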