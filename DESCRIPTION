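Package: sgccaDA
Title: Supervised Sparse Generalized CCA for Multi-Omics Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-omics integration and classification by supervised sparse
    generalized canonical correlation analysis (sGCCA). Fits per-block sparse
    loading vectors that maximize design-weighted covariances between omics
    blocks and a class-indicator outcome block, with soft-thresholding to a
    fixed feature count, deflation across components, centroid-based
    per-block prediction fused by weighted vote, cross-validated sparsity
    tuning, and consensus feature selection over repeated data partitions.
    Includes a latent-factor multi-omics simulator (expression, methylation
    beta values, negative-binomial counts, survival), count-based
    differential expression with TMM normalization and a sloped
    significance/fold-change relevance boundary, Pearson correlation
    screening, and Kaplan-Meier / log-rank survival characterization of
    selected features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    survival,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
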