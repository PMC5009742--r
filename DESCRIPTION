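Package: exparkit
Title: Kinetic Modelling and Quantitative Analysis of Isothermal
    Exponential Amplification (EXPAR) Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models and analyses isothermal exponential amplification
    (EXPAR) assays for short oligonucleotides such as microRNAs. Provides
    a consecutive-reaction kinetic model of EXPAR (closed-form growth
    rate, per-cycle branching outcome, mass-action simulation), a
    synthetic-data generator that emulates plate-reader real-time
    fluorescence and melt curves, point-of-inflection (POI) and melting
    temperature (Tm) extraction from curves, log-linear and two-segment
    calibration fitting with inverse prediction of copy number,
    amplification-template construction for standard, biotin-tagged and
    toehold-exchange designs with nicking-endonuclease site validation
    and nearest-neighbor duplex thermodynamics, and cross-reactivity and
    inter-method accuracy reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    deSolve,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
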