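Package: phstrip
Title: Smartphone Colorimetric pH Strip Readout by Chromatic Adaptation
Version: 0.1.0
Authors@R:
    person("phstrip", "developers", email = "phstrip@example.org",
           role = c("aut", "cre"))
Description: Quantitative readout of paper pH indicator strips from light-box
    photographs. Locates two printed reference color grids and a four-patch
    indicator strip by contour analysis, maps every capture into a common
    chromaticity frame by robust (L1) third-order polynomial chromatic
    adaptation in CIE 1976 u'v' space, interpolates per-patch pH-color curves
    with cubic smoothing splines, and estimates pH by best L1 match against
    the calibrated curves on a 0.1 pH grid. Includes a fully synthetic scene
    generator with ground truth so the whole pipeline is testable without
    hardware, plus a command-line interface for calibration, measurement and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
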