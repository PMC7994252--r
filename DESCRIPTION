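Package: nirsbci
Title: Subject-Independent fNIRS Brain-Computer Interface Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying mental-arithmetic versus idle-state
    trials from functional near-infrared spectroscopy (fNIRS) recordings.
    Converts optical-density changes to oxy-/deoxy-hemoglobin concentration
    changes with the modified Beer-Lambert law, band-pass filters the
    hemodynamic signals, segments them into baseline-corrected epochs, and
    classifies trials with shrinkage linear discriminant analysis, a bagged
    ensemble of regularized LDA, a compact convolutional network (EEGNet),
    and a 1-D convolutional network with evolving normalization-activation
    (EvoNorm) layers. Includes leave-one-subject-out cross-validation, a
    pseudo-online calibration-size simulation, an exact Wilcoxon signed-rank
    test, and a synthetic multi-subject fNIRS data generator so the whole
    pipeline runs without any external dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
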