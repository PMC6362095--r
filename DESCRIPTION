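Package: mdaseq
Title: Lineage and Maturation Analysis of Midbrain Dopamine Neurons from
    Single-Cell RNA-Seq and In Situ Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the developmental heterogeneity of
    Pitx3-positive midbrain dopamine neurons from Smart-seq2 single-cell
    RNA-seq together with targeted in situ RNA sequencing. Implements
    stage-specific library quality-control filtering, spike-in-calibrated
    selection of biologically variable genes, principal-component
    pseudotime with temporal expression-curve clustering, a consensus
    cell-cell graph fused from multiple t-SNE embeddings with infomap
    community detection and marker-rule lineage annotation, a barcode
    decoder for multi-round fluorescence in situ sequencing with per-round
    quality scores, and rank-based random-forest consensus label transfer
    from the dissociated to the spatial modality. A synthetic-data
    generator with planted lineage, maturation and barcode structure makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    randomForest,
    Rtsne,
    splines,
    statmod,
    stats,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
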