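Package: sctopic
Title: Embedded Topic Modelling of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits an embedded topic model to single-cell RNA-seq count
    matrices by amortized variational inference. A neural-network encoder
    maps normalized expression profiles to a logistic-normal posterior over
    per-cell topic mixtures, while a linear tri-factorized decoder (topic
    embeddings times gene embeddings, plus batch-specific gene intercepts)
    reconstructs expression through a multinomial likelihood. Variants
    include adversarial batch correction via a discriminator on the cell
    embedding, and pathway-informed fits in which the gene embedding is
    fixed to a standardized pathways-by-genes membership matrix. The
    package also provides zero-shot transfer of a trained encoder to
    gene-aligned target data, a generative-process simulator with planted
    cell types and batch effects, clustering and batch-mixing evaluation
    (ARI, NMI, kBET, silhouette, Leiden resolution sweep), weighted gene
    set enrichment with a gene-shuffle permutation null, and
    differential-topic permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    cluster,
    mclust,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
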