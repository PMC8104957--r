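Package: retinowin
Title: Display-Independent Visual Stimulation Geometry, Calibration and
    Receptive-Field Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for specifying visual stimuli in retinocentric
    coordinates (degrees of azimuth and elevation) and rendering them,
    via an observer-centred cube map, onto arbitrarily positioned and
    sized displays, projector warp meshes, and stereo eyes, so that the
    same stimulus specification reproduces the same visual-angle image
    on any rig.  Includes automated display-pose calibration from
    photographs of square fiducial markers, display luminance
    linearisation, closed-loop protocol engines (virtual platform,
    augmented-reality windows, sweeping-dot threat, frame-drop
    accounting, freeze and flight classification), and sparse-noise
    reverse-correlation receptive-field mapping with a synthetic-neuron
    generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
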