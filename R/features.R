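#' Delimited string concatenation
#'
#' @param s1,s2 character vectors.
#' @param delim delimiter string placed between \code{s1} and \code{s2}.
#' @return \code{paste0(s1, delim, s2)}.
#' @examples
#' featureConcat("27", "33", "_")  # "27_33"
#' @export
featureConcat <- function(s1, s2, delim = "_") paste0(s1, delim, s2)

#' MD5-compress a feature string
#'
#' Maps a string of arbitrary length to the 32-character lowercase
#' hexadecimal MD5 digest of its UTF-8 bytes, keeping vertex and graph
#' features at a fixed, compact size.  Vectorized.
#'
#' @param s character vector.
#' @return character vector of 32-character hex digests.
#' @examples
#' hashFeature("abc")  # "900150983cd24fb0d6963f7d28e17f72"
#' @export
hashFeature <- function(s) cli::hash_md5(enc2utf8(as.character(s)))

#' Extract the feature library of one graph
#'
#' Iterative Weisfeiler-Lehman-style relabeling with vertex identity
#' awareness.  Starting from caller-supplied per-vertex feature strings, each
#' iteration replaces every vertex's feature by the MD5 hash of its own
#' previous feature concatenated (with \code{"_"}) to the sorted previous
#' features of its neighborhood, and appends the new features to the library.
#' All reads within an iteration come from the previous iteration's snapshot,
#' so the result is independent of sweep order.
#'
#' A vertex of degree zero has no graph neighbors; when
#' \code{zeroDegreeSpecial = TRUE} its "neighborhood" is taken to be the
#' vertices immediately preceding and succeeding it in the vertex ordering,
#' wrapping around (vertex \code{k} precedes vertex 1).  This keeps the
#' identities of silent regions of sparse microcircuits in play.  When
#' \code{FALSE} (plain Weisfeiler-Lehman behavior), a degree-zero vertex is
#' rehashed from its own feature alone.
#'
#' The returned library contains, in order: one graph-level edge-count
#' feature \code{hashFeature(paste0("E", edgeCount(g)))}, the \code{k}
#' initial features, and \code{k} hashed features per iteration -- length
#' \code{1 + k + featureGenIters * k}.
#'
#' @param g an [UnweightedGraph-class].
#' @param initFeatures character vector of length \code{vertexCount(g)};
#'   the initial per-vertex feature strings (see
#'   [initializeVertexLabels()]).
#' @param featureGenIters number of relabeling iterations (>= 1).
#' @param zeroDegreeSpecial logical; use the wrap-around rule for
#'   degree-zero vertices (default \code{TRUE}).
#' @return character vector: the feature library.
#' @examples
#' g <- unweightedGraph(2, rbind(c(1, 2)))
#' extractFeatures(g, c("1", "2"), featureGenIters = 1)
#' @export
extractFeatures <- function(g, initFeatures, featureGenIters = 4L,
                            zeroDegreeSpecial = TRUE) {
  stopifnot(is(g, "UnweightedGraph"))
  k <- vertexCount(g)
  if (length(initFeatures) != k || !is.character(initFeatures))
    stop("initFeatures must be a character vector of length vertexCount(g)")
  featureGenIters <- as.integer(featureGenIters)
  if (is.na(featureGenIters) || featureGenIters < 1L)
    stop("featureGenIters must be a positive integer")

  deg <- degree(g)
  idx <- seq_len(k)
  prv <- c(k, idx[-k])   # wrap-around predecessor
  nxt <- c(idx[-1L], 1L) # wrap-around successor
  e <- edges(g)
  src <- c(e[, 1L], e[, 2L])
  dst <- c(e[, 2L], e[, 1L])
  srcF <- factor(src, levels = idx)
  pos <- deg > 0L

  lib <- vector("list", 2L + featureGenIters)
  lib[[1L]] <- hashFeature(paste0("E", nrow(e)))
  lib[[2L]] <- initFeatures
  cur <- initFeatures
  for (it in seq_len(featureGenIters)) {
    # neighbor features sorted (C-locale radix order) within each vertex
    # group, joined with "_"; one vectorized sweep replaces per-vertex sorts
    if (length(src)) {
      nf <- cur[dst]
      o <- order(src, nf, method = "radix")
      joined <- vapply(split(nf[o], srcF[o]), paste, character(1),
                       collapse = "_")
    } else joined <- character(k)
    raw <- character(k)
    raw[pos] <- paste0(cur[pos], "_", joined[pos])
    if (zeroDegreeSpecial)
      raw[!pos] <- paste0(cur[!pos], "_", cur[prv[!pos]], "_", cur[nxt[!pos]])
    else raw[!pos] <- cur[!pos]
    cur <- hashFeature(raw)
    lib[[it + 2L]] <- cur
  }
  unlist(lib, use.names = FALSE)
}
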