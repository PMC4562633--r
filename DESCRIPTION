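Package: crossnet
Title: Shared Neighbor Gene Discovery Between Pathways via Sparse Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers candidate intermediary ("shared neighbor") genes that
    link two gene pathways from expression matrices. Each pathway gene is
    modeled by elastic-net regression on the pool of genes outside both
    pathways; predictors with non-zero coefficients at the sparsest model
    explaining a target fraction of variance are called neighbors, and genes
    neighboring both pathways are shared neighbors. Includes expression-matrix
    preprocessing (fold-change/floor filtering, z-normalization, upper-quartile
    count normalization), a correlation-distance baseline, knockout/wild-type
    condition set algebra (Venn regions), hypergeometric overrepresentation
    analysis with Benjamini-Hochberg FDR against the predictor-pool background,
    and a synthetic-data generator with planted pathway and intermediary
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
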