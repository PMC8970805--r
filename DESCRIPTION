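Package: miclass
Title: Motor-Imagery EEG Classification with Multiscale PCA, Wavelet
    Scalograms and an Optimized Deep-Feature Decision Tree
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for two-class motor-imagery EEG decoding:
    synthetic generation of C3/Cz/C4 trials with contralateral mu/beta
    event-related desynchronization, multiscale PCA (wavelet subband PCA)
    denoising, continuous-wavelet-transform scalogram images, a compact
    residual convolutional feature extractor trained with focal loss, an
    arithmetic optimization algorithm (AOA) for hyperparameter tuning, an
    ID3 information-gain decision-tree classifier over discretized deep
    features, and confusion-matrix reporting (precision, recall, accuracy,
    F-score, Cohen's kappa). Includes EDF/CSV/RDS trial I/O and a
    config-driven command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
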