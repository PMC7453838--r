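Package: camfit
Title: Extrinsic Camera Calibration and Perspective Mapping for Field Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of oblique field imagery such as
    wildlife-monitoring photographs. Implements a pinhole/cylindrical/
    equirectangular camera model with radial lens distortion, forward
    projection from metric world coordinates to pixels and constrained
    backprojection onto the ground plane, the spherical-earth horizon line,
    and top-view (bird's-eye) orthorectification of images. Unknown extrinsic
    camera parameters (elevation, tilt, roll, heading, position) are
    estimated with full posterior uncertainty by Metropolis Monte-Carlo
    sampling from in-image evidence: known object heights (foot/head click
    pairs), a visible horizon, geo-referenced landmarks, or stereo point
    correspondences. A synthetic-scene generator with known ground truth
    supports validation of every fitting routine without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
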