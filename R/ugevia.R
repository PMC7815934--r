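#' Configuration for the unweighted identity-aware embedder
#'
#' Collects the knobs of [ugevia()]: feature extraction depth, vertex
#' labeling mode and the paragraph-vector (PV-DBOW) hyperparameters.  The
#' document-embedding settings default to learning rate 0.025, downsampling
#' rate 1e-4, minimum count 1 and 100 epochs; relabeling depth defaults to 4
#' iterations and the embedding dimension to 8.
#'
#' @param m embedding dimension (>= 1).
#' @param featureGenIters relabeling iterations (>= 1).
#' @param labelingMode \code{"identity_aware"} (vertex index fused into the
#'   initial label) or \code{"degree_only"} (identity-agnostic baseline in
#'   the graph2vec style).
#' @param zeroDegreeSpecial logical; "Z"-labels plus wrap-around updates for
#'   degree-zero vertices.  Forced off in \code{degree_only} mode.
#' @param learningRate initial PV-DBOW learning rate.
#' @param downsample frequency threshold above which tokens are randomly
#'   downsampled.
#' @param minCount tokens with lower total corpus frequency are ignored.
#' @param epochs training epochs.
#' @param negative negative samples per token.
#' @param seed integer seed for the single-threaded trainer.
#' @return a validated list of class \code{"EmbeddingConfig"}.
#' @export
embeddingConfig <- function(m = 8L, featureGenIters = 4L,
                            labelingMode = c("identity_aware", "degree_only"),
                            zeroDegreeSpecial = TRUE,
                            learningRate = 0.025, downsample = 1e-4,
                            minCount = 1L, epochs = 100L, negative = 5L,
                            seed = 1L) {
  labelingMode <- match.arg(labelingMode)
  if (labelingMode == "degree_only") zeroDegreeSpecial <- FALSE
  cfg <- list(m = as.integer(m), featureGenIters = as.integer(featureGenIters),
              labelingMode = labelingMode,
              zeroDegreeSpecial = isTRUE(zeroDegreeSpecial),
              learningRate = learningRate, downsample = downsample,
              minCount = as.integer(minCount), epochs = as.integer(epochs),
              negative = as.integer(negative), seed = as.integer(seed))
  stopifnot(cfg$m >= 1L, cfg$featureGenIters >= 1L, cfg$epochs >= 1L,
            cfg$learningRate > 0, cfg$minCount >= 0L, cfg$negative >= 1L)
  class(cfg) <- "EmbeddingConfig"
  cfg
}

#' Initial per-vertex feature labels
#'
#' In identity-aware mode every vertex is labeled with its degree fused to
#' its index, \code{"<degree>_<index>"}, so that the same local structure on
#' different neurons yields different features.  Degree-zero vertices get the
#' special label \code{"Z<index>"} when \code{zeroDegreeSpecial = TRUE}; with
#' it disabled they are labeled \code{"0_<index>"} like any other vertex.
#' In \code{degree_only} mode (identity-agnostic baseline) every vertex is
#' labeled with its degree alone.
#'
#' @param g an [UnweightedGraph-class].
#' @param mode \code{"identity_aware"} or \code{"degree_only"}.
#' @param zeroDegreeSpecial logical.
#' @return character vector of length \code{vertexCount(g)}.
#' @examples
#' g <- unweightedGraph(5, rbind(c(1, 2)))
#' initializeVertexLabels(g, "identity_aware")  # "1_1" "1_2" "Z3" "Z4" "Z5"
#' @export
initializeVertexLabels <- function(g,
    mode = c("identity_aware", "degree_only"), zeroDegreeSpecial = TRUE) {
  mode <- match.arg(mode)
  deg <- degree(g)
  idx <- seq_len(vertexCount(g))
  if (mode == "degree_only") return(as.character(deg))
  lab <- paste0(deg, "_", idx)
  if (zeroDegreeSpecial) lab[deg == 0L] <- paste0("Z", idx[deg == 0L])
  lab
}

.graphList <- function(graphs) {
  if (is(graphs, "MicrocircuitDataset")) graphs <- members(graphs)
  if (is(graphs, "UnweightedGraph")) graphs <- list(graphs)
  if (!length(graphs) || !all(vapply(graphs, is, logical(1), "UnweightedGraph")))
    stop("graphs must be UnweightedGraph objects or a MicrocircuitDataset")
  k <- vapply(graphs, vertexCount, integer(1))
  if (length(unique(k)) != 1L)
    stop("all graphs must share one common vertex count")
  graphs
}

#' Build the feature corpus for a set of graphs
#'
#' Labels each graph's vertices with [initializeVertexLabels()] and extracts
#' its feature library with [extractFeatures()]; libraries are collected in
#' input order.
#'
#' @param graphs list of [UnweightedGraph-class] (or a
#'   [MicrocircuitDataset-class] of unweighted members) on one common
#'   vertex set.
#' @param cfg an [embeddingConfig()].
#' @return a [FeatureCorpus-class].
#' @export
buildCorpus <- function(graphs, cfg = embeddingConfig()) {
  graphs <- .graphList(graphs)
  libs <- lapply(graphs, function(g)
    extractFeatures(g,
                    initializeVertexLabels(g, cfg$labelingMode,
                                           cfg$zeroDegreeSpecial),
                    featureGenIters = cfg$featureGenIters,
                    zeroDegreeSpecial = cfg$zeroDegreeSpecial))
  new("FeatureCorpus", libraries = libs)
}

#' Embed a feature corpus with PV-DBOW paragraph vectors
#'
#' Treats each graph's feature library as a bag-of-words document and trains
#' distributed bag-of-words paragraph vectors with negative sampling
#' (single-threaded, deterministic given the seed).  Tokens below
#' \code{minCount} total frequency are dropped; high-frequency tokens are
#' randomly downsampled at rate \code{downsample}; the learning rate decays
#' linearly over training.
#'
#' @param corpus a [FeatureCorpus-class] (nonempty).
#' @param m embedding dimension.
#' @param cfg an [embeddingConfig()] supplying the trainer hyperparameters;
#'   \code{m} overrides \code{cfg$m} when given.
#' @param seed overrides \code{cfg$seed} when given.
#' @return numeric matrix with one row per document (graph) and \code{m}
#'   columns; row i is the embedding of graph i.
#' @export
embedCorpus <- function(corpus, m = cfg$m, cfg = embeddingConfig(),
                        seed = cfg$seed) {
  stopifnot(is(corpus, "FeatureCorpus"))
  libs <- libraries(corpus)
  if (!length(libs)) stop("corpus must be nonempty")
  toks <- unlist(libs, use.names = FALSE)
  vocab <- unique(toks)
  counts <- tabulate(match(toks, vocab), nbins = length(vocab))
  keep <- counts >= max(1L, cfg$minCount)
  vocab <- vocab[keep]
  counts <- counts[keep]
  docs <- lapply(libs, function(lb) {
    ids <- match(lb, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
  emb <- pvdbow_train(docs, as.numeric(counts), as.integer(m),
                      cfg$epochs, cfg$learningRate, cfg$downsample,
                      cfg$negative, as.integer(seed))
  stopifnot(all(is.finite(emb)))
  emb
}

#' Identity-aware embedding of unweighted graphs
#'
#' Composes [buildCorpus()] and [embedCorpus()]: every input graph gets a
#' feature library built from identity-aware iterative relabeling, and the
#' libraries are embedded jointly as documents.  Two isomorphic graphs whose
#' edges sit on different vertex indices receive distinguishable embeddings
#' -- the property that identity-agnostic whole-graph embeddings lack.
#'
#' @inheritParams buildCorpus
#' @return numeric matrix, one row per graph, \code{cfg$m} columns.
#' @seealso [wgevia()] for weighted datasets.
#' @export
ugevia <- function(graphs, cfg = embeddingConfig()) {
  embedCorpus(buildCorpus(graphs, cfg), m = cfg$m, cfg = cfg,
              seed = cfg$seed)
}
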