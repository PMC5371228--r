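Package: methclock
Title: Mouse Liver Epigenetic Clock Analysis from Bisulfite Methylation Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for building and evaluating a DNA
    methylation ("epigenetic") clock from per-CpG bisulfite sequencing
    calls in mouse liver. Implements coverage-file import and matrix
    assembly, the site/sample filtering and mean-imputation profiles used
    for cross-species comparison and clock construction, covariate-adjusted
    drop-one F-tests for age association with Benjamini-Hochberg FDR
    control, a normalized methylome entropy statistic, empirical-Bayes
    location/scale batch correction (parametric and nonparametric priors),
    elastic-net age regression with cross-validated hyperparameter
    selection and a covariate-shuffle permutation control, cross-species
    ortholog mapping with region enrichment and hypergeometric overlap
    tests, and downstream evaluation of lifespan-extending treatments
    (residual t-tests/ANOVA, PCA of clock sites, hierarchical clustering).
    A synthetic cohort generator with known ground truth exercises the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
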