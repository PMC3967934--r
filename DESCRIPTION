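Package: flif
Title: Fractional Leaky Integrate-and-Fire Neuron Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the fractional leaky integrate-and-fire
    (FLIF) neuron, a spiking neuron model in which the membrane voltage obeys a
    Caputo fractional-order differential equation discretized with the L1
    finite-difference scheme. The fractional order controls a power-law
    voltage-memory trace that produces spike-frequency adaptation, long
    first-spike latencies, history-dependent firing and high spike-time
    reliability. Includes generators for the standard stimulation protocols
    (current steps, conditioning pre-pulses, ZAP chirps, sine and square waves,
    alpha-filtered noise), quantification routines (inter-spike-interval
    statistics, membrane impedance, firing-rate gain and phase, adaptation time
    constants, correlation-based spike-time reliability), a Mittag-Leffler
    closed-form reference solution with a memory-reset spiking variant, and
    mean-squared-error fitting of the fractional exponent to reference curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    minpack.lm,
    withr
Config/testthat/edition: 3
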