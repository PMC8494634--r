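Package: censuskit
Title: Cross-Species Cell-Type Census and Regulatory-Genomics Toolkit
Version: 0.1.0
Authors@R:
    person("Census", "Toolkit Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for building cross-species consensus cell-type taxonomies
    from single-cell expression data (metacell aggregation, Ward trees,
    subsample-based node assessment, recursive stability pruning, dendrogram
    bootstrap confidence, ROC marker selection), cross-species cluster
    statistics (Spearman profile correlation, pseudobulk negative-binomial
    Wald tests, conserved and species-enriched marker partitions), candidate
    cis-regulatory element construction (summit extension, score-per-million
    normalization, iterative overlap merging that avoids daisy-chaining),
    enhancer-gene linking with an empirical normal-fit FDR null, nonnegative
    matrix factorization of accessibility into cis-regulatory modules with
    sparseness-based rank selection, and projection-enrichment and exact
    rank-test statistics.  A synthetic-data module plants known ground truth
    so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
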