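Package: grnae
Title: Gene Regulatory Network Inference from Single-Cell Expression with a Graph Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers directed, signed gene regulatory networks from single-cell
    RNA-seq expression matrices. A weighted gene co-expression prior graph is
    built from absolute Spearman rank correlations, renormalized as in graph
    convolutional networks, and fed to a graph autoencoder whose GCN encoder
    embeds genes and whose bilinear decoder scores every regulator-target
    pair. Includes BEELINE-style evaluation (AUROC, AUPRC, early precision
    ratio, AUPRC ratio, signed RMSE, topology analytics), edge-level k-fold
    cross-validation with negative sampling, and a seeded Hill-kinetics
    simulator of single-cell expression along differentiation trajectories
    for six benchmark network archetypes with dropout injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
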