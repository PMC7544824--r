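Package: sensorspan
Title: Predicted Measurement Accuracy of Two-State Ratiometric Biosensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts how empirical fluorescence-ratio measurement error limits
    the range of biochemical values (glutathione redox potential, pH, ligand
    concentration) that a two-state ratiometric biosensor can measure to a stated
    accuracy. Provides closed-form forward and inverse calibration maps between
    the fluorescence ratio, the state fraction, and the biochemical value;
    propagation of multiplicative ratio errors into value-space confidence bounds,
    inaccuracy curves, and suitable measurement ranges; sensor comparison
    (best-sensor envelopes, optimal windows, coverage gaps, feasibility phase
    diagrams); derivation of conversion factors from two-state excitation or
    emission spectra with optimal filter-band search; a sensor-parameter database;
    synthetic fixtures for testing; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
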