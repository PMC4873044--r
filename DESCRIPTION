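Package: smoothpls
Title: Penalized Multi-Way Partial Least Squares for Smooth Trajectory Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tensor-based decoders for continuous trajectory reconstruction from
    multichannel neural recordings. Implements N-way partial least squares (NPLS)
    regression between a 4-way time-frequency-space feature tensor and a motion
    trajectory, together with two smoothness-penalized variants: a Sobolev-norm
    penalty on the s-th derivative of the predicted stream (SNPLS) and a
    Savitzky-Golay polynomial-smoothing penalty (PNPLS), both realized as data
    augmentation followed by the same NPLS core. Also provides a Kalman-filter
    decoder baseline with least-squares system identification, Morlet
    continuous-wavelet feature extraction, normalized accuracy and smoothness
    criteria (correlation, RMSE, MAE, MADE), prediction-delay estimation,
    modality-influence analysis, chronologically blocked cross-validation, and
    seeded synthetic generators for trajectories, feature tensors and raw
    band-modulated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
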