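Package: afmfibril
Title: Comparative Structural Analysis of Amyloid Fibrils from AFM and Cryo-EM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating atomic force microscopy (AFM) topographs of
    individual helical amyloid fibrils with cryo-EM density maps. Simulates
    tip-convolved AFM height images from map iso-surfaces (sphere-capped cone
    tip contact model), reconstructs three-dimensional surface envelopes of
    single fibrils from straightened AFM topographs by tip deconvolution and
    helical phase accumulation, detects helical symmetry, and ranks the
    structural similarity of an imaged fibril against a library of candidate
    structures by a correlation-distance image score combined with normalized
    morphometric distances (symmetry, handedness, cross-over distance,
    cross-sectional area and shape difference). Includes helical phantom
    generators so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    mgcv,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
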