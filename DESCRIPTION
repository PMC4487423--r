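Package: microed
Title: Conversion, Calibration and Screening of Continuous-Rotation
    Electron Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning raw continuous-rotation micro-electron
    diffraction (MicroED) frame stacks into geometry-complete diffraction
    images in the Super Marty View (SMV) format, ready for standard
    crystallographic integration packages.  Includes the supporting
    calibration procedures (detector gain from background statistics,
    beam-centre refinement from inversion symmetry, bad-pixel detection
    from temporal statistics, camera-length calibration against powder
    rings), sweep-quality screening (spot finding, autoindexing
    feasibility, rocking-curve extraction), and a synthetic diffraction
    simulator with exhaustive ground truth so that every stage can be
    exercised without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
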