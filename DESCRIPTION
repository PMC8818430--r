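Package: viemdar
Title: Visual-Imagery EEG Classification via Empirical Mode Decomposition
    and Autoregressive Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification of two-class visual-imagery
    electroencephalography (EEG). Implements empirical mode decomposition (EMD)
    with cubic-spline envelope sifting, Hilbert-Huang instantaneous-energy
    features, autoregressive (AR) model features with Burg estimation and
    AIC/FPE order selection, and a hybrid EMD+AR feature extractor that fits
    least-squares AR models to energy-normalised intrinsic mode functions.
    Includes a synthetic multichannel EEG generator with alpha-band class
    contrast on frontal channels, an elliptic band-pass preprocessing chain
    with ICA-based artifact rejection, support-vector-machine evaluation with
    stratified splits, and per-band / per-channel group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
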