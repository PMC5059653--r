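Package: coldburst
Title: Coupled Phase-Temperature Dynamics of Mammalian Cold-Receptor Bursting
Version: 0.1.0
Authors@R:
    person("coldburst", "maintainers", email = "coldburst@example.org",
           role = c("aut", "cre"))
Description: Simulates burst firing of mammalian cold thermoreceptors with a
    nonstochastic phase-oscillator model whose drift parameters saturate
    sigmoidally in temperature, and couples the phase equation to a Morse-like
    relaxation of an effective temperature to reproduce the transient peak
    response seen after sudden cooling. Provides fixed-step Runge-Kutta
    integration of steady and transient scenarios, spike and burst analytics
    (spikes per burst, burst period, overlap widths, interspike-interval
    histograms), calibration of the saturating parameter forms against the
    classical linear forms, a bisection search for the temperature-relaxation
    width parameter, and a deterministic command-line scenario runner with
    TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
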