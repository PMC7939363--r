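Package: morphozoo
Title: Random Developmental Mechanisms, Morphological Complexity and the
    Genotype-Phenotype Map
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale ensemble framework for studying how morphological
    complexity relates to the genotype-phenotype map in development.  It
    couples random gene regulatory networks to cell behaviors and tissue
    mechanics in a 3D cell-center model of an epithelial sheet, simulates
    development under noise, scores the resulting morphologies with
    angle-variation and orientation-patch-count complexity measures, and
    compares morphologies with homology-free and lineage-homology distances.
    Mutational screens (pruning, one-mutant neighborhoods, iso-morphological
    random walks) and regression statistics quantify developmental
    instability, mutational asymmetry and the complexity of the
    genotype-phenotype map across an ensemble of mechanisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
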