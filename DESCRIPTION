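Package: tissuehop
Title: Tissue-Constrained Knowledge-Graph Inference for Indication Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and characterizes a dated, publication-weighted
    heterogeneous knowledge graph over genes, diseases and tissues, and
    predicts new gene-disease (indication-expansion) links from it.
    Provides tissue-constrained one- and two-hop path inference with
    publication-count path scores and path-level explanations, a
    degree-preserving gene-label-shuffle null model with one-sided z-tests,
    prospective time-split validation (training graph, post-cutoff gold
    standard, candidate-pair universe), translational and bilinear
    knowledge-graph embeddings (TransE, TransH, TransD, DistMult, random
    walks) with a random-forest link classifier, ranked and per-disease
    evaluation metrics, and a seeded synthetic-graph generator with planted
    post-cutoff links for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    Matrix,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
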