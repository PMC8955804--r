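Package: skinfab
Title: Multilayered Skin Mockup Fabrication from RGB Skin Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts an RGB photograph of human skin into a multilayered,
    printer-ready representation. Melanin and hemoglobin concentration maps
    are separated with color-plane PCA, two-dimensional independent
    component analysis and oblique shading removal under a modified
    Lambert-Beer model; concentrations are calibrated to CMYK with three
    interchangeable estimators (lookup table, log-linear regression, small
    neural network) evaluated by leave-one-out cross-validation; colored
    layers are halftoned by Floyd-Steinberg error diffusion; and a
    clear/melanin/clear/hemoglobin/clear/white layer stack is assembled
    into a print job. A forward optical model and virtual press stand in
    for the physical print-and-photograph loop so every stage is testable
    without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
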