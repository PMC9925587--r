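Package: bisym
Title: Bilateral Symmetry Analysis of Paired Bone Surface Meshes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies bilateral (left-right) shape symmetry of paired 3D
    bone surface meshes, with a workflow tailored to the proximal tibia.
    One side is mirrored across a sagittal plane, rigidly superimposed onto
    the contralateral side with a Coherent Point Drift (CPD) registration,
    both surfaces are cut in an axial plane a fixed depth below the tibial
    plateau, re-registered on the retained proximal band, and
    correspondence-point Euclidean distances are summarised (mean, RMS,
    maximum, percentiles) and exported as per-vertex heatmap fields.
    Includes PLY/STL/OBJ mesh input and output, a parametric generator of
    proximal-tibia-like bilateral mesh pairs with known injected asymmetry
    for validation, cohort-level aggregation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
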