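# Independent oracles used across the suite.

# Spearman rank correlation from the textbook difference formula (valid when
# there are no ties): 1 - 6 * sum(d^2) / (n (n^2 - 1)).
refSpearmanNoTies <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Reference feature-library construction: a deliberately naive per-vertex
# re-implementation of the relabeling sweep with an explicit previous-iteration
# snapshot, using neighbor lookups straight from the edge matrix.
refLibrary <- function(g, init, iters, zeroDegreeSpecial = TRUE) {
  k <- vertexCount(g)
  e <- edges(g)
  lib <- c(hashFeature(paste0("E", nrow(e))), init)
  cur <- init
  for (it in seq_len(iters)) {
    snapshot <- cur
    nxt <- character(k)
    for (v in seq_len(k)) {
      nbr <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
      if (length(nbr)) {
        joined <- paste(sort(snapshot[nbr], method = "radix"),
                        collapse = "_")
        nxt[v] <- hashFeature(paste0(snapshot[v], "_", joined))
      } else if (zeroDegreeSpecial) {
        p <- if (v == 1) k else v - 1
        s <- if (v == k) 1 else v + 1
        nxt[v] <- hashFeature(paste0(snapshot[v], "_", snapshot[p], "_",
                                     snapshot[s]))
      } else {
        nxt[v] <- hashFeature(snapshot[v])
      }
    }
    lib <- c(lib, nxt)
    cur <- nxt
  }
  lib
}

# Random simple graph on k vertices with ne edges (no self-loops/duplicates).
randomGraph <- function(k, ne, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pick <- pairs[sample.int(nrow(pairs), min(ne, nrow(pairs))), , drop = FALSE]
  unweightedGraph(k, pick)
}

# Mean silhouette width of 2-D points under a binary partition.
silhouetteWidth <- function(coords, labels) {
  D <- as.matrix(dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_along(labels) != i])
    b <- mean(D[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
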