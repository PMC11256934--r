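Package: pathimpute
Title: Path-Based Heterogeneous Graph Imputation for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reference-free imputation of dropout zeros in spatial
    transcriptomic count matrices using a path-based heterogeneous graph
    neural network. Cells are connected by two complementary edge sets --
    spatial proximity and expression similarity over highly variable genes
    -- and node embeddings are convolved along second-order (Node2Vec)
    random walks with learnable per-position path operators, avoiding the
    over-smoothing of Laplacian message passing at large receptive fields.
    Includes the masked-entry evaluation protocol (held-out nonzero
    entries scored by L1 distance, cosine similarity and RMSE), a
    synthetic layered-tissue data generator with known ground truth, a
    mean-aggregation GCN baseline, and desk-scale receptive-field,
    graph-modality and operator-sharing ablation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rhdf5
Config/testthat/edition: 3
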