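Package: ribosurf
Title: Surface Morphometrics of Membrane-Associated Ribosomes in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how cytoplasmic ribosomes sit on organellar membranes in
    cryo-electron tomograms. Given subtomogram particle tables (STAR dialect) and
    triangle-mesh reconstructions of the outer and inner mitochondrial membranes,
    the package computes particle-to-mesh distances and orientations, classifies
    ribosomes oriented for co-translational protein import, measures second-order
    spatial clustering on the membrane with a Ripley's K ratio against a Monte
    Carlo complete-spatial-randomness null, detects polysome-like chains from
    mRNA entry/exit port geometry, builds membrane patches and overlap-fraction
    statistics against cristae-junction regions, and compares intermembrane
    distances at co-translation sites. A parametric synthetic-scene generator
    produces double-membrane meshes with ground-truth particle placements so the
    whole pipeline is testable without tomographic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
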