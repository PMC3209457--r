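Package: flexmotif
Title: Elastic-Network Analysis of Mutation Effects on Binding-Motif Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking how a point mutation perturbs the flexibility of
    a functional binding motif in a protein, at coarse-grained (C-alpha) scale.
    Builds anisotropic elastic-network models from PDB structures, performs
    normal mode analysis with residue cross-correlation maps and B-factor
    profiles, represents mutations as local spring-constant perturbations,
    runs overdamped Langevin dynamics on the network potential with
    trajectory RMSD and windowed B-factor statistics, and provides
    Hardy-Weinberg carrier-frequency arithmetic for recessive-disease
    alleles. Includes seeded generators of toy folded C-alpha chains so the
    whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    jsonlite,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
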