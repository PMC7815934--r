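#' Configuration for the multi-channel weighted embedder
#'
#' @param nc number of channels (default 10).
#' @param muC per-channel embedding dimension (default 8); the output
#'   embedding has \code{nc * muC} columns.
#' @param base an [embeddingConfig()] used for every per-channel run of
#'   [ugevia()]; its \code{m} is replaced by \code{muC} and its seed is
#'   offset by the channel index so the whole pipeline is reproducible.
#' @return a validated list of class \code{"ChannelConfig"}.
#' @export
channelConfig <- function(nc = 10L, muC = 8L, base = embeddingConfig()) {
  cfg <- list(nc = as.integer(nc), muC = as.integer(muC), base = base)
  stopifnot(cfg$nc >= 1L, cfg$muC >= 1L, inherits(base, "EmbeddingConfig"))
  class(cfg) <- "ChannelConfig"
  cfg
}

#' Maximum edge weight across a weighted dataset
#'
#' @param d a weighted [MicrocircuitDataset-class] with at least one edge.
#' @return the maximum weight over all edges of all members.
#' @export
datasetMaxWeight <- function(d) {
  stopifnot(is(d, "MicrocircuitDataset"), isWeighted(d))
  w <- unlist(lapply(members(d), edgeWeights), use.names = FALSE)
  if (!length(w)) stop("dataset has no edges")
  max(w)
}

#' Threshold ladder for channel construction
#'
#' The j-th of \code{nc} thresholds is
#' \deqn{T_j = w_{max} / (2 n_c) + (j - 1) \, w_{max} / n_c,}
#' i.e. the ladder starts at \code{wmax/(2*nc)} and climbs in steps of
#' \code{wmax/nc}.  For weights uniform on \code{[0, wmax]} this retains on
#' average 95\%, 85\%, ..., 5\% of edges across 10 channels.
#'
#' @param wmax positive maximum edge weight of the dataset.
#' @param nc number of channels (>= 1).
#' @return numeric vector of \code{nc} increasing thresholds.
#' @examples
#' computeThresholds(1, 10)  # 0.05 0.15 ... 0.95
#' @export
computeThresholds <- function(wmax, nc) {
  nc <- as.integer(nc)
  if (!is.finite(wmax) || wmax <= 0) stop("wmax must be positive")
  if (is.na(nc) || nc < 1L) stop("nc must be a positive integer")
  wmax / (2 * nc) + (seq_len(nc) - 1L) * wmax / nc
}

#' Binarize a weighted dataset at one threshold
#'
#' For each member, starts from the edgeless graph on the common vertex set
#' and adds an unweighted edge for every edge whose weight strictly exceeds
#' \code{T}.
#'
#' @param d a weighted [MicrocircuitDataset-class].
#' @param T threshold; edges with \code{W(e) > T} are retained.
#' @return list of [UnweightedGraph-class], one per member.
#' @export
thresholdChannel <- function(d, T) {
  stopifnot(is(d, "MicrocircuitDataset"), isWeighted(d))
  k <- vertexCount(d)
  lapply(members(d), function(mcc) {
    keep <- edgeWeights(mcc) > T
    unweightedGraph(k, edges(mcc)[keep, , drop = FALSE])
  })
}

#' Single-threshold weighted-to-unweighted conversion
#'
#' Baseline conversion used to feed weighted microcircuits to unweighted
#' embedders: an edge is removed when \code{W(e) <= chi} and retained (weight
#' discarded) otherwise.  Elementwise identical to
#' \code{thresholdChannel(d, chi)}.
#'
#' @param d a weighted [MicrocircuitDataset-class].
#' @param chi removal threshold (default 0.196, the tuned value used for the
#'   unweighted baselines).
#' @return list of [UnweightedGraph-class].
#' @export
weightedToUnweighted <- function(d, chi = 0.196) thresholdChannel(d, chi)

#' Multi-channel identity-aware embedding of weighted graph datasets
#'
#' Derives \code{nc} unweighted \emph{channels} from the weighted dataset by
#' thresholding the edge weights along the ladder of [computeThresholds()]
#' (computed from the dataset-wide maximum weight), embeds every channel with
#' [ugevia()] at dimension \code{muC}, and concatenates each graph's
#' per-channel vectors in channel order.  Low channels keep most edges and
#' capture coarse structure; high channels isolate the strongest couplings.
#'
#' @param d a weighted [MicrocircuitDataset-class] with at least one edge.
#' @param cfg a [channelConfig()].
#' @return numeric matrix with \code{nGraphs(d)} rows and \code{nc * muC}
#'   columns; the j-th block of \code{muC} columns comes from channel j.
#' @export
wgevia <- function(d, cfg = channelConfig()) {
  emb <- do.call(cbind, wgeviaChannels(d, cfg))
  stopifnot(ncol(emb) == cfg$nc * cfg$muC)
  emb
}

#' Per-channel embeddings of a weighted dataset
#'
#' Same construction as [wgevia()] but returning the per-channel embedding
#' matrices separately (e.g. for [tsneChannels()] visualization).
#'
#' @inheritParams wgevia
#' @return list of \code{nc} matrices, each \code{nGraphs(d) x muC}.
#' @export
wgeviaChannels <- function(d, cfg = channelConfig()) {
  thr <- computeThresholds(datasetMaxWeight(d), cfg$nc)
  base <- cfg$base
  lapply(seq_len(cfg$nc), function(j) {
    chCfg <- base
    chCfg$m <- cfg$muC
    chCfg$seed <- base$seed + j
    ugevia(thresholdChannel(d, thr[j]), chCfg)
  })
}
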