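Package: coexmod
Title: Gene Co-Expression Modules, Eigengene Scoring and Projection for
    Toxicogenomic Fold-Change Data
Version: 0.1.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Builds unsigned weighted gene co-expression modules from a
    treatment-by-gene log2 fold-change matrix (soft-power adjacency,
    topological overlap, hierarchical tree cut, eigengene-correlation
    merging), computes normalized module eigengene scores with per-gene
    eigengene correlations (corEG) and hub genes, and freezes the result
    so that external datasets -- including sparse targeted gene panels --
    can be projected onto the same module space with zero-fill for
    unmeasured genes. Also provides permutation-based module preservation
    statistics (Z-summary, median rank), hypergeometric over-representation
    analysis of pathways and transcription-factor regulons, surrogate TF
    activity scores, SVD imputation and seed-module cluster expansion for
    compound-similarity maps, donor-trait association via Cohen's d and
    covariate-adjusted logistic regression, and seeded synthetic-data
    generators with planted module structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
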