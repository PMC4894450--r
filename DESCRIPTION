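Package: crescentshape
Title: Single-Cell Shape Dynamics of Crescent-Shaped Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the shape dynamics of growing and dividing
    Caulobacter crescentus cells from phase-contrast time-lapse movies.
    Provides a ground-truthed synthetic movie generator, sub-pixel contour
    extraction (smoothing filter, bottom-hat segmentation, periodic smoothing
    of boundary pixels), medial-axis morphometry (length, centerline radius,
    width profiles, invagination detection), cell-cycle phase ensemble
    statistics with cross-generation inheritance tracking, a mechanical
    cell-wall energy model with septal constriction kinetics and Laplace pole
    asymmetry, and nonlinear least-squares fits of the growth and constriction
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    tiff,
    png
Config/testthat/edition: 3
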