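.normalizeEdges <- function(edges, k) {
  if (is.null(edges) || length(edges) == 0L)
    return(list(edges = matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("u", "v"))),
                order = integer(0)))
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L)
    stop("edges must be a two-column matrix of vertex indices")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edges contain NA")
  if (any(edges < 1L) || any(edges > k))
    stop(sprintf("edge endpoints must lie in 1..%d", k))
  u <- pmin(edges[, 1L], edges[, 2L])
  v <- pmax(edges[, 1L], edges[, 2L])
  if (any(u == v)) stop("self-loops are not allowed")
  ord <- order(u, v)
  out <- cbind(u[ord], v[ord])
  dimnames(out) <- list(NULL, c("u", "v"))
  key <- (out[, 1L] - 1) * as.double(k) + out[, 2L]
  if (anyDuplicated(key)) stop("duplicate edges")
  list(edges = out, order = ord)
}

#' Construct an unweighted graph
#'
#' @param vertexCount number of vertices \code{k}; vertices are \code{1..k}
#'   and the index of a vertex is its identifier.
#' @param edges two-column matrix (or \code{NULL}) of vertex index pairs;
#'   orientation and row order are normalized internally.
#' @return an [UnweightedGraph-class] object.
#' @examples
#' g <- unweightedGraph(5, rbind(c(1, 2), c(2, 3)))
#' degree(g, 2)
#' @export
unweightedGraph <- function(vertexCount, edges = NULL) {
  k <- as.integer(vertexCount)
  e <- .normalizeEdges(edges, k)$edges
  new("UnweightedGraph", vertexCount = k, edges = e)
}

#' Construct a weighted microcircuit graph
#'
#' @inheritParams unweightedGraph
#' @param weights numeric vector of edge weights aligned with the rows of
#'   \code{edges} as given (they are re-ordered together with the edges).
#' @return a [Microcircuit-class] object.
#' @examples
#' m <- microcircuit(5, rbind(c(1, 2), c(4, 5)), weights = c(0.8, -0.1))
#' edgeWeights(m)
#' @export
microcircuit <- function(vertexCount, edges = NULL, weights = numeric(0)) {
  k <- as.integer(vertexCount)
  nz <- .normalizeEdges(edges, k)
  w <- as.numeric(weights)
  if (length(w) != nrow(nz$edges))
    stop("weights must have exactly one entry per edge")
  new("Microcircuit", vertexCount = k, edges = nz$edges,
      weights = w[nz$order])
}

#' Construct a microcircuit dataset
#'
#' @param members list of [UnweightedGraph-class] or [Microcircuit-class]
#'   objects sharing one vertex count.
#' @param labels optional binary labels (0/1), one per member.
#' @return a [MicrocircuitDataset-class] object.
#' @export
microcircuitDataset <- function(members, labels = NULL) {
  if (!length(members)) stop("members must be a nonempty list of graphs")
  k <- members[[1L]]@vertexCount
  lab <- if (is.null(labels)) integer(0) else as.integer(labels)
  new("MicrocircuitDataset", members = members, vertexCount = k,
      labels = lab)
}
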