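Package: thzcornea
Title: Terahertz Time-Domain Spectroscopy Analysis of Corneal Endothelial Integrity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for terahertz time-domain
    spectroscopy (THz-TDS) of the cornea. Generates physically motivated
    synthetic cohorts of reflection-mode corneal scans (double-Debye water
    permittivity, Bruggeman effective-medium mixing, Fickian hydration
    profiles, transfer-matrix stratified reflectance), processes per-pixel
    pulses into deconvolved band-limited spectral slopes, aggregates them
    into per-sample hydration features, and classifies endothelial integrity
    with linear support-vector machines evaluated over repeated randomized
    train/test splits with averaged ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
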