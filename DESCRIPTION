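Package: fracHH
Title: Fractional-Order Hodgkin-Huxley Neuron, Axon, and Network Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of excitable membranes whose capacitive current obeys a
    fractional-order (constant-phase-element) current-voltage relationship.
    Provides a Grunwald-Letnikov explicit integrator for fractional-order
    differential equations with full-history, truncated, and compressed
    (sum-of-exponentials) memory policies; the fractional-order Hodgkin-Huxley
    membrane patch, one-dimensional active cable (method of lines), and random
    conductance-based networks built on it; closed-form fractional
    passive-membrane theory (Mittag-Leffler step responses, strength-duration
    curves, constant-phase-element impedance, passive-cable Green's functions
    and sub-threshold pseudo-velocity); and electrophysiological metrics
    (spike detection, threshold and refractory-interval searches, repetitive
    firing statistics, spiking-range scans, propagation velocity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
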