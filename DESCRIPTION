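Package: mvtrack
Title: Multi-Camera Three-Dimensional Multi-Target Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Offline re-implementation of a real-time multi-camera tracking
    pipeline for small flying animals. Extracts sub-pixel 2D features from
    grayscale frames by running-Gaussian background subtraction and image
    moments, estimates 3D position and velocity per target with an extended
    Kalman filter over a projective multi-camera observation model, links
    observations to targets with gated nearest-neighbour data association,
    and manages automatic track birth (triangulation hypothesis testing)
    and death (covariance threshold). Includes DLT calibration and
    triangulation, a synthetic camera-rig/trajectory/image simulator with
    ground truth, and flight-trajectory statistics (horizontal speed,
    angular velocity, approach angle, speed histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
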