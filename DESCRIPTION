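Package: mveks
Title: Multi-View Ensemble Kalman Smoothing for Animal Pose Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric and probabilistic post-processing toolkit for
    multi-camera animal pose estimation. Provides camera models with radial
    and tangential distortion, DLT triangulation with multi-pair averaging,
    linear (PCA-subspace) and nonlinear (camera-model) multi-view Ensemble
    Kalman filter-smoothers with automatic smoothing-parameter selection,
    cross-view Mahalanobis inconsistency detection with iterative variance
    inflation, uncertainty-guided pseudo-label frame selection,
    training-side heatmap operators (soft argmax, Gaussian heatmaps,
    reprojection loss, patch-mask curriculum, 3D-consistent augmentation),
    and a synthetic multi-camera scene simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
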