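#' Template structures for the five-vertices benchmark
#'
#' Six unweighted graphs on the common vertex set \code{1..5}.  The pairs
#' (3, 4) and (5, 6) are isomorphic with equal edge counts but edges on
#' different vertex indices, so they are indistinguishable to any
#' identity-agnostic embedder; templates 1 and 2 differ in edge count.
#' Plenty of degree-zero vertices exercise the special zero-degree labeling.
#'
#' @return list of six [UnweightedGraph-class] templates.
#' @export
fiveVerticesTemplates <- function() {
  list(
    unweightedGraph(5, rbind(c(1, 2))),                      # delta 1
    unweightedGraph(5, rbind(c(1, 2), c(2, 3), c(3, 4))),    # delta 2
    unweightedGraph(5, rbind(c(1, 2))),                      # delta 3
    unweightedGraph(5, rbind(c(3, 4))),                      # delta 4
    unweightedGraph(5, rbind(c(1, 2), c(2, 3))),             # delta 5
    unweightedGraph(5, rbind(c(3, 4), c(4, 5)))              # delta 6
  )
}

# brute-force isomorphism over all vertex permutations (k! small here)
.isoByPermutation <- function(g1, g2) {
  k <- vertexCount(g1)
  if (vertexCount(g2) != k || edgeCount(g1) != edgeCount(g2)) return(FALSE)
  key <- function(e) paste(e[, 1L], e[, 2L], sep = "-", collapse = ";")
  target <- key(edges(g2))
  perms <- .permutations(k)
  e1 <- edges(g1)
  for (p in perms) {
    pe <- cbind(p[e1[, 1L]], p[e1[, 2L]])
    u <- pmin(pe[, 1L], pe[, 2L]); v <- pmax(pe[, 1L], pe[, 2L])
    ord <- order(u, v)
    if (key(cbind(u[ord], v[ord])) == target) return(TRUE)
  }
  FALSE
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- vector("list", k * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(k)) {
    i <- i + 1L
    out[[i]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Generate the five-vertices benchmark dataset
#'
#' Builds the benchmark of \code{6 * copies} unweighted graphs on the common
#' vertex set \code{1..5}: six blocks of identical copies of the templates,
#' in template order, labeled 0 for templates 1, 3, 5 and 1 for templates
#' 2, 4, 6.  At the default 500 copies this is the 3,000-graph benchmark;
#' the many identical copies exist purely so downstream classifiers have
#' enough training instances.
#'
#' Template invariants are validated on entry: templates 3/4 and 5/6 must be
#' isomorphic (checked by brute force over all 5! vertex permutations) with
#' different edge supports, and templates 1/2 must differ in edge count.
#'
#' @param copies copies per template block (default 500).
#' @param templates list of six templates (default
#'   [fiveVerticesTemplates()]).
#' @return a labeled, unweighted [MicrocircuitDataset-class] of
#'   \code{6 * copies} graphs.
#' @export
generateFiveVertices <- function(copies = 500L,
                                 templates = fiveVerticesTemplates()) {
  copies <- as.integer(copies)
  stopifnot(copies >= 1L, length(templates) == 6L)
  k <- unique(vapply(templates, vertexCount, integer(1)))
  if (length(k) != 1L)
    stop("templates must share one common vertex set")
  sameEdges <- function(a, b) identical(edges(a), edges(b))
  for (pair in list(c(3L, 4L), c(5L, 6L))) {
    a <- templates[[pair[1L]]]; b <- templates[[pair[2L]]]
    if (!.isoByPermutation(a, b) || sameEdges(a, b))
      stop(sprintf(
        "templates %d and %d must be isomorphic with different edge supports",
        pair[1L], pair[2L]))
  }
  if (edgeCount(templates[[1L]]) == edgeCount(templates[[2L]]))
    stop("templates 1 and 2 must differ in edge count")

  membersList <- rep(templates, each = copies)
  labels <- rep(rep(c(0L, 1L), 3L), each = copies)
  microcircuitDataset(membersList, labels = labels)
}

#' Select one pairwise five-vertices experiment
#'
#' Experiment \code{i} is the union of template blocks \code{2i - 1} and
#' \code{2i}: experiment 1 contrasts different edge counts; experiments 2
#' and 3 contrast isomorphic structures placed on different vertex
#' identities.
#'
#' @param i experiment index, 1, 2 or 3.
#' @param dataset a dataset from [generateFiveVertices()] (block ordering
#'   assumed).
#' @return a balanced labeled [MicrocircuitDataset-class] of
#'   \code{2 * copies} graphs.
#' @export
selectExperiment <- function(i, dataset = generateFiveVertices()) {
  i <- as.integer(i)
  if (is.na(i) || !(i %in% 1:3)) stop("experiment index must be 1, 2 or 3")
  n <- nGraphs(dataset)
  if (n %% 6L != 0L) stop("dataset is not a six-block five-vertices dataset")
  copies <- n %/% 6L
  idx <- ((2L * i - 2L) * copies + 1L):((2L * i) * copies)
  dataset[idx]
}
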