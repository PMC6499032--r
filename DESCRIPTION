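Package: rasr
Title: Artifact Subspace Reconstruction for Multichannel EEG with
    Riemannian Covariance Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Online and offline correction of multichannel EEG artifacts by
    artifact subspace reconstruction (ASR) and its Riemannian variant (rASR).
    A statistical model of clean calibration data (robust covariance, mixing
    matrix, per-component amplitude thresholds) is learned once and then used
    to detect and reconstruct artifact-dominated subspaces in short sliding
    windows. Covariance matrices can be handled either with Euclidean
    running averages and PCA, or on the manifold of symmetric
    positive-definite matrices using Karcher means and principal geodesic
    analysis. Includes a synthetic mobile-EEG session generator (1/f
    background, frontal eye-blinks, occipital visual-evoked potentials) with
    ground truth, and an evaluation module scoring blink suppression,
    VEP retention and decomposition-count efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
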