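Package: dyadshare
Title: Mother-Infant Gut Microbiome Sharing and Strain Transmission Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-cohort analysis of gut microbiome sharing between
    mothers and their infants. Implements species-level presence/absence sharing
    and cross-cohort core-set identification, strain-level vertical-transmission
    calling from marker-gene SNP haplotypes (neighbor-joining trees, normalized
    patristic distances, conservative 0.1 threshold), stratified (study-blocked)
    rank-sum and Kruskal-Wallis tests with Benjamini-Hochberg correction,
    PERMANOVA-based covariate variance partitioning over sampling-time bins,
    arcsine-square-root linear models for covariate associations, and
    leave-one-study-out machine-learning prediction of shared species and strain
    occurrence in infants from maternal species profiles. A synthetic multi-study
    dyad-cohort generator with known ground-truth transmission events makes every
    stage testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    Biostrings,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
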