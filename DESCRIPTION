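Package: rivasm
Title: Community Assembly Analysis for Dammed-River Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for analysing microbial community assembly
    along cascade-dammed rivers from OTU count tables, phylogenies and sample
    metadata: alpha diversity on rarefied counts (Shannon, Chao1, Faith's PD),
    Bray-Curtis beta diversity with PCoA, PERMANOVA and multivariate
    dispersion tests, distance-decay regression against dam-count spatial
    separation, Mantel and multiple regression on distance matrices with
    Benjamini-Hochberg families, phylogenetic and taxonomic null models
    (abundance-weighted betaMNTD/betaNTI and Raup-Crick on Bray-Curtis) with
    five-way assembly-process partitioning, Sloan's neutral community model
    fit, and occupancy-specificity specialist and core-taxon analysis.
    Includes a synthetic metacommunity generator emulating a ten-reach,
    two-season, four-replicate sampling design with tunable selection,
    dam-mediated dispersal limitation and drift, so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    picante,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
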