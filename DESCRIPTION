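Package: wallperm
Title: Hydraulic Permeability and Resistance of the Arterial Wall from
    Voxel Microstructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying pressure-dependent water transport across
    the arterial wall. Generates synthetic medial microstructures (smooth
    muscle cells embedded in extracellular matrix) and confocal-like
    fluorescence stacks, segments stacks into cell and matrix compartments,
    homogenizes voxelized blocks into an effective permeability tensor via
    a finite-volume Darcy solver and least-squares inversion, performs
    biphasic mixture-theory bookkeeping (solid volume fractions, volumetric
    ratio), fits a deformation-dependent permeability constitutive law and
    sigmoid pressure relations with AICc model selection, and decomposes
    whole-wall hydraulic resistance into intimal and medial contributions
    in series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
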