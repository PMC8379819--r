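Package: fatdep
Title: Co-Expression Network Analysis of Fat-Deposition Transcriptomes
Version: 1.0.0
Authors@R: person("fatdep", "maintainers", role = c("aut", "cre"),
    email = "maintainers@fatdep.dev")
Description: An offline, fully testable pipeline for identifying candidate
    genes of porcine fat deposition from multi-tissue RNA-seq count data:
    low-expression filtering, median-of-ratios size factors, a closed-form
    variance-stabilizing transformation, per-tissue negative-binomial Wald
    differential expression with Cook's-distance outlier flagging,
    candidate-gene set algebra across breeds, weighted gene co-expression
    network construction (soft-threshold scan with scale-free fit,
    topological overlap), module detection and eigengene-based merging,
    module-trait association, hub-gene ranking, and hypergeometric gene-set
    enrichment against user-supplied GMT collections. Ships a synthetic-data
    generator with planted modules, trait effects and differential genes so
    every stage is validated against ground truth.
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
    withr,
    DESeq2
Config/testthat/edition: 3
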