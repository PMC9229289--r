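Package: ecgid
Title: ECG Biometric Identification with Wavelet Fiducial Detection and a
    WOA-Tuned Probabilistic Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies individuals from single-lead electrocardiogram
    recordings. Fiducial points are delineated with an undecimated quadratic
    spline wavelet transform (R peaks from modulus-maxima pairs on scale 4,
    Q and S on scale 1, P and T peaks plus onsets and offsets via locally
    windowed wavelet transforms). Twenty-two interval and amplitude features
    per heartbeat feed a probabilistic neural network classifier whose
    smoothing factor is tuned by the whale optimization algorithm; mean
    impact value screening ranks and prunes the features. A synthetic
    multi-subject ECG simulator with exact fiducial ground truth supports
    evaluation without access to clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
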