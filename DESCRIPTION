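Package: fohtrack
Title: Needle-Tip Tracking from Fibre-Optic Hydrophone Ultrasound Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localising a needle tip carrying a fibre-optic
    hydrophone (FOH) inside the field of a curvilinear ultrasound imaging
    probe. Segments digitizer streams into per-frame waveform arrays using
    line and frame triggers, applies matched filtering and envelope
    detection, estimates the tip's polar coordinates from the energy
    distribution across scan lines and the pulse time of arrival, and scan
    converts to Cartesian image coordinates with full covariance
    propagation. Includes a synthetic curvilinear-field simulator for a
    point receiver, an evaluation harness for accuracy, repeatability and
    signal-to-noise experiments, optional Kalman smoothing of tracks, and
    B-mode image calibration and overlay utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
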