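Package: fwavetilt
Title: F-Wave Frequency Tracking and Respiratory Modulation Analysis for
    Tilt-Test ECGs in Atrial Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying autonomic effects on atrial fibrillatory
    waves during head-up/head-down tilt testing. Implements QRST cancellation
    and f-wave extraction from multi-lead ECGs, maximum-likelihood harmonic
    tracking of the f-wave frequency trend with signal-quality gating,
    ECG-derived respiration via the QRS slope range and periodic component
    analysis, orthogonal-subspace-projection quantification of respiratory
    f-wave frequency modulation, an activation-time analysis for simulated
    atrial electrograms, six-phase tilt segmentation with paired
    nonparametric phase statistics, and a synthetic tilt-ECG generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nortest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
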