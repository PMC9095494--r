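Package: plexusQC
Title: Detecting Choroid Plexus Contamination in Brain Transcriptome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control pipeline for detecting choroid plexus tissue
    contamination in bulk brain RNA expression datasets. Computes within-sample
    percentile ranks of choroid plexus marker genes (TTR, FOLR1, PRLR),
    classifies datasets into five contamination-pattern priorities from
    group-wise ANOVA on marker ranks, assigns samples to low/high contamination
    groups by log2 marker-expression thresholds, and confirms contamination by
    a normalization and differential-expression stage (CPM filtering, trimmed
    mean of M-values scaling, mean-variance precision weights, weighted linear
    models with sex and age covariates, empirical-Bayes moderated t-statistics)
    followed by hypergeometric gene-set enrichment. Includes a negative-binomial
    tissue/contaminant mixture simulator with known per-sample contamination
    fractions for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
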