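Package: myoreach
Title: Closed-Loop Simulation of Myoelectric Cursor Control with Virtual
    Admittance Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying real-time myoelectric (sEMG) cursor control.
    Implements the two classic control schemes -- antagonist-pair direct
    control with co-contraction or trigger-based mode switching, and
    pattern-recognition control built on time-domain features and a
    single-hidden-layer neural network -- together with the shared envelope
    and MVC-calibration pipeline and a first-order admittance (mass-damper)
    cursor model. A seeded synthetic sEMG generator emulating healthy and
    dystrophic (DMD-like) forearm muscle profiles closes the loop, so full
    target-reaching sessions, reaching-time statistics and histograms can be
    simulated and analysed without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    signal,
    stats,
    utils,
    withr,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
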