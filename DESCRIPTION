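Package: waxomics
Title: Integrative Genetic Analysis of Leaf Cuticular Wax Traits and
    Cuticular Conductance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic basis of natural variation in
    leaf cuticular wax composition and its relationship to cuticular
    conductance (g_c) in diversity panels of inbred lines. Implements trait
    quality control for zero-inflated wax abundances, REML mixed-model BLUPs
    and line-mean heritability from multi-environment trials, Box-Cox
    transformation with outlier screening, kinship-controlled
    mixed-linear-model genome-wide and transcriptome-wide association scans
    with a likelihood-ratio R2 statistic, Fisher's combined test integration
    of GWAS and TWAS evidence, sliding-window detection of multi-trait GWAS
    hotspots, candidate-gene declaration and confidence grouping, and
    random-forest prediction of conductance from wax profiles with repeated
    cross-validation and permutation importance. A seeded synthetic-data
    generator produces genotypes with linkage disequilibrium and population
    structure, cis-regulated expression with latent confounders, and
    correlated zero-inflated wax traits with a machine-readable truth record
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    randomForest,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
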