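Package: dyadgaze
Title: Dual-Camera Gaze Estimation and Gaze Synchrony Analysis for
    Face-to-Face Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric and statistical toolkit for simultaneous video-based
    gaze estimation of two face-to-face interlocutors observed by a pair of
    opposed cameras sharing one 3D coordinate frame.  Provides a two-sphere
    eye model (pupil-offset gaze and iris-ellipse unprojection), facial
    landmark head-pose estimation from caliper-measured geometry, face-plane
    construction and line-plane gaze intersection, Kalman smoothing and
    blink/outlier exclusion of detector output, affine face-plane
    calibration, nearest-landmark area-of-interest classification, and
    windowed time-lagged cross-correlation analysis of interpersonal gaze
    synchrony.  A ground-truth dyad simulator generates detector-level
    observation streams for validation and power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
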