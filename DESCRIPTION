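Package: scalpnet
Title: Spectrogram Transformer and Electrode-Graph Fusion for EEG Classification
Version: 0.1.0
Authors@R: person("scalpnet", "developers", role = c("aut", "cre"),
    email = "scalpnet@example.org")
Description: A two-stage pipeline for classifying multichannel scalp EEG
    recordings. Raw recordings on the international 10-20 montage are
    band-pass and notch filtered, average-referenced, z-scored and cut into
    60-second segments of twenty 3-second pieces; short-time Fourier
    transforms of the pieces are concatenated into per-channel power-density
    spectrogram maps. A small-data vision transformer with shifted patch
    tokenization and locality self-attention (diagonal masking, learnable
    softmax temperature) extracts per-channel time-frequency features, and a
    spectral graph convolutional network fuses them over the scalp-electrode
    adjacency graph. Includes a synthetic resting-state EEG cohort generator
    with class-distinct spectral signatures, subject-wise cross-validation,
    macro-averaged metrics with one-vs-rest ROC/AUC, EDF input/output and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
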