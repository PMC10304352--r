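Package: swirtrack
Title: Digital Twin of a Short-Wave Infrared Real-Time Insect Tracker
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses short-wave infrared (SWIR) detector
    frames for real-time tracking of photoluminescent-tagged flying
    insects. Provides a ground-truthed scene simulator (3-D correlated
    random-walk flight trajectories, pinhole projection, Gaussian tag
    blobs with roll-dependent visibility, fixed-pattern hot pixels, 8-bit
    quantization), the streaming raster-order threshold detector with
    hot-pixel skipping that emulates the on-sensor FPGA processing,
    dark-frame hot-pixel calibration, a last-known-position waypoint
    tracker, and the optical geometry and hard-real-time latency and
    data-rate accounting of the detector design. Frames are exchanged as
    binary PGM, tracks and masks as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
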