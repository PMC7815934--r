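Package: wgevia
Title: Identity-Aware Graph-Level Embedding of Weighted Microcircuit Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-level embeddings for functional microcircuit graphs that
    preserve vertex (neuron) identities. Implements an unweighted
    identity-aware embedder built on iterative Weisfeiler-Lehman-style
    vertex relabeling with MD5-compressed feature strings and a paragraph
    vector (PV-DBOW) document embedder, and its weighted multi-channel
    extension that binarizes a weighted dataset along a threshold ladder
    and concatenates per-channel embeddings. Includes the five-vertices
    identity-awareness benchmark generator, a leaky integrate-and-fire
    network simulator with Spearman-window microcircuit construction, and
    a downstream classification harness (MLPs, RBF-SVM, LDA) with
    stratified 10-fold cross-validation, balanced accuracy, paired t-tests
    and per-channel t-SNE visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cli,
    Rcpp,
    e1071,
    MASS,
    Rtsne
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    openssl,
    igraph,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
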