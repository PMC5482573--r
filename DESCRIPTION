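Package: tomocoat
Title: Subtomogram Averaging and Difference-Density Analysis for Coated-Vesicle CryoET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale cryo-electron tomography pipeline for membrane-coat
    lattices such as the COPI coat. Generates synthetic coated-vesicle scenes
    with known ground truth, simulates dose-symmetric tilt-series acquisition
    with CTF and exposure-dependent dose filtering, reconstructs tomograms by
    weighted back-projection, and performs missing-wedge-aware subtomogram
    averaging: constrained cross-correlation alignment, wedge-compensated
    averaging, Cn symmetry handling, half-set refinement with gold-standard
    Fourier shell correlation, local resolution estimation and B-factor
    sharpening. Includes multireference classification for localizing
    substoichiometric extra densities (e.g. ArfGAP binding), model-versus-map
    difference mapping with connected-component segmentation and ranking,
    rigid-body fitting, cross-link distance screening, and neighbor-pose
    linkage clustering for lattice geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
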