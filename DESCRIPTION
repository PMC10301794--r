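Package: electrodecam
Title: ECG Electrode Localization from 3D Depth-Sensing Camera Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline pipeline that reconstructs the positions and channel
    labels of body-surface ECG electrodes from multi-view recordings of a
    3D depth-sensing camera. Covers chromaticity-based automatic white
    balancing and color-temperature correction, histogram-skewness exposure
    scoring, Canny-style depth-image segmentation, textured surface meshing,
    symmetric point-to-plane ICP multi-view registration, red-disk/blue-ring
    fiducial marker detection and model fitting, electrode grid construction
    by ball pivoting, channel label assignment, and marker color calibration.
    Includes a synthetic torso-scene renderer with known ground truth so the
    whole pipeline can be exercised and validated without camera hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    yaml,
    tibble,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
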