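#' @describeIn UnweightedGraph-class number of vertices.
#' @param x an object.
#' @export
setMethod("vertexCount", "UnweightedGraph", function(x) x@vertexCount)

#' @describeIn UnweightedGraph-class two-column integer edge matrix.
#' @export
setMethod("edges", "UnweightedGraph", function(x) x@edges)

#' @describeIn UnweightedGraph-class number of edges.
#' @export
setMethod("edgeCount", "UnweightedGraph", function(x) nrow(x@edges))

#' @describeIn Microcircuit-class numeric edge weights, aligned with
#'   \code{edges(x)} rows.
#' @param x an object.
#' @export
setMethod("edgeWeights", "Microcircuit", function(x) x@weights)

#' @describeIn UnweightedGraph-class vertex degree(s): the number of edges
#'   incident to each vertex in \code{v}.
#' @param v vertex index (or vector of indices) in \code{1..vertexCount(x)}.
#' @export
setMethod("degree", "UnweightedGraph", function(x, v) {
  k <- x@vertexCount
  if (missing(v)) v <- seq_len(k)
  v <- as.integer(v)
  if (anyNA(v) || any(v < 1L) || any(v > k))
    stop(sprintf("vertex index out of range 1..%d", k))
  deg <- tabulate(x@edges, nbins = k)
  deg[v]
})

#' @describeIn UnweightedGraph-class whether the graph carries edge weights.
#' @export
setMethod("isWeighted", "UnweightedGraph", function(x) is(x, "Microcircuit"))

setMethod("show", "UnweightedGraph", function(object) {
  cat(sprintf("%s with %d vertices, %d edges\n", class(object),
              object@vertexCount, nrow(object@edges)))
  if (nrow(object@edges))
    cat("  first edges:",
        paste(apply(head(object@edges, 5L), 1L, paste, collapse = "-"),
              collapse = " "), "\n")
})

#' @describeIn MicrocircuitDataset-class list of member graphs.
#' @param x an object.
#' @export
setMethod("members", "MicrocircuitDataset", function(x) x@members)

#' @describeIn MicrocircuitDataset-class number of member graphs.
#' @export
setMethod("nGraphs", "MicrocircuitDataset", function(x) length(x@members))

#' @describeIn MicrocircuitDataset-class common vertex count.
#' @export
setMethod("vertexCount", "MicrocircuitDataset", function(x) x@vertexCount)

#' @describeIn MicrocircuitDataset-class binary labels (\code{integer(0)}
#'   when the dataset is unlabeled).
#' @export
setMethod("graphLabels", "MicrocircuitDataset", function(x) x@labels)

#' @describeIn MicrocircuitDataset-class whether members carry weights.
#' @export
setMethod("isWeighted", "MicrocircuitDataset", function(x)
  length(x@members) > 0L && is(x@members[[1L]], "Microcircuit"))

setMethod("show", "MicrocircuitDataset", function(object) {
  cat(sprintf("MicrocircuitDataset: %d %s graphs on %d common vertices\n",
              length(object@members),
              if (isWeighted(object)) "weighted" else "unweighted",
              object@vertexCount))
  if (length(object@labels))
    cat(sprintf("  labels: %d x 0, %d x 1\n",
                sum(object@labels == 0L), sum(object@labels == 1L)))
})

#' Extract members of a dataset
#'
#' @param x a [MicrocircuitDataset-class].
#' @param i index vector.
#' @param j,drop,... ignored.
#' @return a [MicrocircuitDataset-class] with the selected members (labels
#'   subset alongside).
#' @export
setMethod("[", "MicrocircuitDataset", function(x, i, j, ..., drop = FALSE) {
  lab <- if (length(x@labels)) x@labels[i] else NULL
  microcircuitDataset(x@members[i], labels = lab)
})

#' @describeIn FeatureCorpus-class list of per-graph feature libraries.
#' @param x an object.
#' @export
setMethod("libraries", "FeatureCorpus", function(x) x@libraries)

setMethod("show", "FeatureCorpus", function(object) {
  n <- length(object@libraries)
  len <- if (n) lengths(object@libraries) else integer(0)
  cat(sprintf("FeatureCorpus: %d documents, %s features each\n", n,
              if (n && length(unique(len)) == 1L) unique(len)
              else paste0(min(len), "-", max(len))))
})

#' @describeIn ActivityTrace-class neurons x frames membrane potential matrix.
#' @param x an object.
#' @export
setMethod("potentials", "ActivityTrace", function(x) x@potentials)

#' @describeIn ActivityTrace-class neurons x frames binary spike matrix.
#' @export
setMethod("spikes", "ActivityTrace", function(x) x@spikes)

setMethod("show", "ActivityTrace", function(object) {
  cat(sprintf("ActivityTrace: %d neurons x %d frames, %d spikes\n",
              nrow(object@potentials), ncol(object@potentials),
              sum(object@spikes)))
})
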