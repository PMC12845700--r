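Package: frozemg
Title: Frozen Multi-Scale Random Convolution Features for Surface EMG
    Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A training-free pipeline for surface electromyography (sEMG)
    gesture classification. Motion segments are cut from labelled
    recordings and their boundaries refined by multi-channel generalized
    likelihood ratio (GLR) change-point detection; each channel is
    decomposed by variational mode decomposition (VMD) with DC correction,
    least-squares amplitude calibration and quality gating; intrinsic mode
    functions are ranked by a weighted combination of energy ratio,
    Pearson correlation and sample entropy; raw and mode branches are
    mapped through frozen multi-scale dilated random convolution banks to
    global-average-pooling and positive-proportion statistics; and a
    closed-form L2-regularized linear readout performs classification.
    Includes a synthetic sEMG generator with known class structure and
    motion boundaries so every stage is testable at desk scale, plus exact
    McNemar and Holm-Bonferroni utilities for paired classifier
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
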