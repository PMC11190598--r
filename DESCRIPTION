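Package: emghht
Title: Hand-Gesture Classification from Surface EMG via the
    Hilbert-Huang Transform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for classifying hand gestures from
    single-channel surface electromyography (sEMG) epochs: wavelet
    threshold denoising, empirical mode decomposition (EMD) with the
    Hilbert analytic-signal step, per-IMF statistical features
    (mean power, spread, energy, entropy), and a feedforward neural
    network with leaky-ReLU hidden units and softmax output trained by
    backpropagation. Includes a seeded synthetic sEMG generator that
    emulates a 5-s active / 5-s rest acquisition protocol with two
    gesture vocabularies (ten finger movements, six hand grasps), a
    trial-based train/test split, and confusion-matrix evaluation with
    per-class accuracy, sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
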