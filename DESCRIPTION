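Package: eegfatigue
Title: Multi-Class EEG Driver-Fatigue Detection with GAN Augmentation and
    Chebyshev Graph Convolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale, fully seeded pipeline for multi-class driver
    fatigue detection from multi-channel EEG. Provides a synthetic EEG
    cohort generator with an ordinal fatigue gradient encoded in
    theta/alpha/beta band powers, the standard signal-conditioning chain
    (channel selection, 50 Hz notch, 0.02-50 Hz Butterworth band-pass,
    terminal windowing, min-max normalization), per-class generative
    adversarial augmentation of windowed EEG, functional-connectivity
    channel graphs with Chebyshev spectral machinery, a five-layer
    Chebyshev graph-convolutional classifier with exact parameter
    accounting, and evaluation tools (confusion-matrix metrics, Cohen's
    kappa, one-vs-rest ROC, SNR robustness sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
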