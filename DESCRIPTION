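Package: cellgate
Title: Polygon Gating and Region Statistics for Single-Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Manual cell selection for single-cell transcriptomics without a
    mouse: polygon "gates" defined on any two-dimensional embedding (UMAP,
    t-SNE, PCA) or on gene/antibody-capture scatter axes classify cells by an
    even-odd point-in-polygon rule, write per-cell annotation labels, and
    persist gate sessions as JSON. Downstream read-outs per gated region or
    cluster include percentage of cells, percentage of cells expressing a
    gene, transcripts per million (TPM) from raw UMI counts, and
    fold-enrichment of a gene inside versus outside a population. A Gaussian
    mixture model with k-means++ initialization groups cells on two marker
    genes as a clustering alternative to gating. A negative-binomial
    synthetic-data generator with clustered embeddings, marker genes, dropout
    and log-normal antibody-capture counts makes every step testable without
    external downloads. A command-line interface ties the steps into headless
    workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    ggplot2,
    methods,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
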