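Package: phenofactor
Title: Latent Behavioral Domains via Factor Analysis and Consensus
    Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Discovery of robust, interpretable latent domains in
    subjects-by-variables behavioral tables. Provides preprocessing
    (variable screening, family-preserving splits, chained-equation
    imputation, confound regression, z-scoring), maximum-likelihood
    exploratory factor analysis with varimax rotation, parallel analysis,
    subsample robustness with Hungarian factor matching, Bartlett factor
    scores and a cross-level factor hierarchy, resampling consensus
    clustering with consensus-score diagnostics, and confirmatory factor
    analysis with standard fit indices (CFI, TLI, RMSEA, SRMR).  A
    synthetic-data generator with planted factor structure supports
    end-to-end validation by parameter recovery.
License: MIT + file LICENSE
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    jsonlite,
    methods,
    S4Vectors,
    stats,
    utils
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
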