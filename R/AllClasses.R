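#' Unweighted graph on an indexed vertex set
#'
#' Undirected simple graph whose vertices are the consecutive integers
#' \code{1..vertexCount}.  The index of a vertex is its identifier: graphs in
#' one microcircuit dataset share the vertex set, and vertex \code{i} means
#' the same neuron in every member.  Edges are stored as a two-column integer
#' matrix with \code{edges[, 1] < edges[, 2]}, rows sorted lexicographically,
#' so that serialization and feature extraction are deterministic.
#'
#' @slot vertexCount single integer, number of vertices \code{k}.
#' @slot edges integer matrix with two columns; each row one undirected edge.
#'
#' @seealso [unweightedGraph()], [Microcircuit-class]
#' @export
setClass("UnweightedGraph",
  representation(vertexCount = "integer", edges = "matrix"))

setValidity("UnweightedGraph", function(object) {
  k <- object@vertexCount
  e <- object@edges
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("vertexCount must be a single positive integer")
  if (!is.integer(e) || ncol(e) != 2L)
    return("edges must be a two-column integer matrix")
  if (nrow(e) > 0L) {
    if (anyNA(e)) return("edges contain NA")
    if (any(e < 1L) || any(e > k))
      return(sprintf("edge endpoints must lie in 1..%d", k))
    if (any(e[, 1L] >= e[, 2L]))
      return("edges must satisfy edges[,1] < edges[,2] (no self-loops)")
    key <- (e[, 1L] - 1) * as.double(k) + e[, 2L]
    if (anyDuplicated(key)) return("duplicate edges")
    if (is.unsorted(key)) return("edge rows must be sorted lexicographically")
  }
  TRUE
})

#' Weighted microcircuit graph
#'
#' A microcircuit model is an unweighted graph together with a real weight per
#' edge; here weights are typically Spearman correlations between the activity
#' of the two incident neurons.  Extends [UnweightedGraph-class]; the
#' \code{weights} slot is aligned with the rows of the edge matrix.
#'
#' @slot weights numeric vector, one value per edge.
#' @seealso [microcircuit()], [MicrocircuitDataset-class]
#' @export
setClass("Microcircuit",
  contains = "UnweightedGraph",
  representation(weights = "numeric"))

setValidity("Microcircuit", function(object) {
  if (length(object@weights) != nrow(object@edges))
    return("weights must have exactly one entry per edge")
  if (anyNA(object@weights) || any(!is.finite(object@weights)))
    return("weights must be finite")
  TRUE
})

#' Indexed collection of microcircuit graphs on one common vertex set
#'
#' Holds \code{nGraphs} members (all [UnweightedGraph-class] or all
#' [Microcircuit-class]) that share the common vertex set \code{1..k}, plus
#' optional binary labels aligned with the members (e.g. a behavioral
#' condition per imaging time window).
#'
#' @slot members list of graphs.
#' @slot vertexCount single integer, common vertex count \code{k}.
#' @slot labels integer vector of 0/1 labels, or \code{integer(0)} when absent.
#' @seealso [microcircuitDataset()], [readDataset()]
#' @export
setClass("MicrocircuitDataset",
  representation(members = "list", vertexCount = "integer",
                 labels = "integer"))

setValidity("MicrocircuitDataset", function(object) {
  k <- object@vertexCount
  if (length(k) != 1L || is.na(k) || k < 1L)
    return("vertexCount must be a single positive integer")
  ok <- vapply(object@members, function(g)
    is(g, "UnweightedGraph") && g@vertexCount == k, logical(1))
  if (!all(ok))
    return("all members must be UnweightedGraph/Microcircuit on the common vertex set")
  lab <- object@labels
  if (length(lab)) {
    if (length(lab) != length(object@members))
      return("labels must align with members")
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      return("labels must be binary (0/1)")
  }
  TRUE
})

#' Feature corpus: one feature library per graph
#'
#' Ordered list pairing each input graph (by position) with its feature
#' library -- the list of raw and MD5-hashed feature strings that serves as
#' the document for the paragraph-vector embedding step.
#'
#' @slot libraries list of character vectors, one per graph, in input order.
#' @seealso [buildCorpus()], [extractFeatures()]
#' @export
setClass("FeatureCorpus", representation(libraries = "list"))

setValidity("FeatureCorpus", function(object) {
  ok <- vapply(object@libraries, is.character, logical(1))
  if (!all(ok)) return("libraries must be character vectors")
  TRUE
})

#' Per-neuron activity traces from the integrate-and-fire simulation
#'
#' @slot potentials numeric matrix, neurons x frames, membrane potential.
#' @slot spikes integer matrix of the same shape, 1 where the neuron spiked.
#' @seealso [simulateCondition()], [buildMicrocircuits()]
#' @export
setClass("ActivityTrace",
  representation(potentials = "matrix", spikes = "matrix"))

setValidity("ActivityTrace", function(object) {
  if (!all(dim(object@potentials) == dim(object@spikes)))
    return("potentials and spikes must have identical dimensions")
  if (any(!is.finite(object@potentials)))
    return("potentials must be finite")
  if (!all(object@spikes %in% c(0L, 1L)))
    return("spikes must be binary")
  TRUE
})
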