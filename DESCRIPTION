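Package: circuitrate
Title: Firing-Rate Dynamics of Cortical RS-LTS-FS Circuits with Short-Term Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of firing-rate models of neocortical
    circuits composed of regular-spiking (RS) pyramidal cells and
    low-threshold-spiking (LTS) and fast-spiking (FS) inhibitory interneurons,
    with Tsodyks-Markram short-term synaptic depression and facilitation.
    Provides a fixed-step fourth-order Runge-Kutta integrator with constant,
    step and periodic square-wave stimulus protocols; closed-form and numerical
    steady states with linear stability; recruitment thresholds and response
    delays of the LTS population; attractor classification and oscillation
    metrics; two-parameter regime (phase) diagrams and fixed-ratio input
    sweeps; and a fast-slow (relaxation-oscillation) analysis of the
    facilitation-driven slow oscillation in a reduced circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    pracma,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
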