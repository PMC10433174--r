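Package: ratoonGS
Title: Ratooning-Ability Traits, Mixed-Model GWAS, and Genomic Prediction
    for Clonal Sugarcane Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ratooning-ability (RA) traits for sugarcane clones from
    multi-cycle field trials and evaluates their genetic architecture and
    predictability. Composite sugar and yield traits (sugar content, cane
    yield, commercial recoverable sugar, sucrose yield, economic index) are
    computed from plot-level component measurements; per-cycle clone effects
    are estimated with REML mixed models (a univariate augmented row-column
    field model with heterogeneous residual classes, and a multivariate
    multi-cycle model with unstructured genetic and residual covariance);
    RA is the average ratoon performance as a percentage of plant cane.
    Marker-trait associations are scanned with a kinship-corrected
    mixed-model GWAS under pseudo-diploid gene-action codings with
    leave-one-chromosome-out relationship matrices and Benjamini-Hochberg
    thresholds, and four genomic-prediction models (ridge-regression BLUP,
    Bayes A, reproducing-kernel Hilbert space regression, and an
    additive-dominance-epistasis kernel model) are benchmarked by repeated
    k-fold cross-validation, optionally carrying a within-fold GWAS peak
    marker as a fixed covariate. A synthetic-population module simulates
    clonal panels, augmented row-column designs, and multi-cycle phenotypes
    with controlled heritability and cross-cycle genetic correlation so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
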