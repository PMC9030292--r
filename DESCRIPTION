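Package: circsponge
Title: Staged circRNA Differential Expression, Circular-to-Linear
    Proportions and miRNA Sponge Network Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for circular RNA expression across ordered
    cell maturation stages. Implements negative-binomial Wald tests for
    pairwise stage contrasts with Benjamini-Hochberg adjustment,
    circular-to-linear expression proportions (CLP) from paired
    back-splice-junction and host-gene count matrices, z-score pattern
    clustering and PCA of expression profiles, and construction plus
    Type 0/1/2 classification of circRNA-miRNA-mRNA sponge networks from
    binding-site and target-prediction score tables. Ships a
    negative-binomial synthetic-data generator with planted effects so
    every stage of the pipeline can be validated against a known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    igraph,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
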