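#' Read a microcircuit dataset from a plain-text edge-list file
#'
#' The dialect is line-oriented UTF-8 text: a header line \code{"k n_G"}
#' giving the common vertex count and the number of graphs, then for each
#' graph a record line \code{"graph <index> [<label>]"} followed by one line
#' per edge, \code{"u v"} (unweighted) or \code{"u v w"} (weighted).  Vertex
#' indices are 1-based.  Either every graph carries a 0/1 label or none does.
#'
#' @param path file to read.
#' @param weighted logical; whether edge lines carry a weight column.
#' @return a [MicrocircuitDataset-class].
#' @seealso [writeDataset()]
#' @export
readDataset <- function(path, weighted = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  bad <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg),
                               call. = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop(sprintf("%s: empty file", path), call. = FALSE)
  tok <- strsplit(trimws(lines[nonEmpty]), "[[:space:]]+")

  hd <- tok[[1L]]
  if (length(hd) != 2L || anyNA(suppressWarnings(as.integer(hd))))
    bad(nonEmpty[1L], "expected header 'k n_G'")
  k <- as.integer(hd[1L]); ng <- as.integer(hd[2L])
  if (k < 1L || ng < 0L) bad(nonEmpty[1L], "header values must be positive")

  isHeaderRec <- vapply(tok, function(t) t[1L] == "graph", logical(1))
  isHeaderRec[1L] <- FALSE
  recAt <- which(isHeaderRec)
  if (length(recAt) != ng)
    stop(sprintf("%s: header promises %d graphs, found %d 'graph' records",
                 path, ng, length(recAt)), call. = FALSE)

  labels <- rep(NA_integer_, ng)
  membersList <- vector("list", ng)
  bounds <- c(recAt, length(tok) + 1L)
  ecols <- if (weighted) 3L else 2L
  for (gi in seq_len(ng)) {
    ri <- recAt[gi]
    rt <- tok[[ri]]
    if (!(length(rt) %in% c(2L, 3L)))
      bad(nonEmpty[ri], "expected 'graph <index> [<label>]'")
    if (length(rt) == 3L) {
      lab <- suppressWarnings(as.integer(rt[3L]))
      if (is.na(lab) || !(lab %in% c(0L, 1L)))
        bad(nonEmpty[ri], "label must be 0 or 1")
      labels[gi] <- lab
    }
    rows <- seq(ri + 1L, bounds[gi + 1L] - 1L)
    if (bounds[gi + 1L] - 1L < ri + 1L) rows <- integer(0)
    ne <- length(rows)
    em <- matrix(integer(0), ncol = 2L)
    w <- numeric(0)
    if (ne) {
      lens <- lengths(tok[rows])
      if (any(lens != ecols))
        bad(nonEmpty[rows[which(lens != ecols)[1L]]],
            sprintf("expected %d fields on edge line%s", ecols,
                    if (weighted) " (u v w)" else " (u v)"))
      flat <- unlist(tok[rows], use.names = FALSE)
      fm <- matrix(flat, nrow = ne, byrow = TRUE)
      uv <- suppressWarnings(cbind(as.integer(fm[, 1L]),
                                   as.integer(fm[, 2L])))
      if (anyNA(uv))
        bad(nonEmpty[rows[which(is.na(rowSums(uv)))[1L]]],
            "non-integer vertex index")
      if (any(uv < 1L | uv > k))
        bad(nonEmpty[rows[which(rowSums(uv < 1L | uv > k) > 0)[1L]]],
            sprintf("edge endpoint outside 1..%d", k))
      em <- uv
      if (weighted) {
        w <- suppressWarnings(as.numeric(fm[, 3L]))
        if (anyNA(w))
          bad(nonEmpty[rows[which(is.na(w))[1L]]], "non-numeric edge weight")
      }
    }
    membersList[[gi]] <- tryCatch(
      if (weighted) microcircuit(k, em, w) else unweightedGraph(k, em),
      error = function(e) bad(nonEmpty[ri], conditionMessage(e)))
  }
  if (any(!is.na(labels)) && any(is.na(labels)))
    stop(sprintf("%s: either all graphs must be labeled or none", path),
         call. = FALSE)
  microcircuitDataset(membersList,
                      labels = if (all(!is.na(labels))) labels else NULL)
}

#' Write a microcircuit dataset as a plain-text edge-list file
#'
#' Emits the dialect accepted by [readDataset()].  Edges are written in the
#' normalized order (sorted by (min, max) endpoint) so output is
#' deterministic; weights are printed with 17 significant digits so a
#' read-back reproduces them to within 1e-12.
#'
#' @param d a [MicrocircuitDataset-class].
#' @param path file to write.
#' @return \code{invisible(path)}.
#' @export
writeDataset <- function(d, path) {
  stopifnot(is(d, "MicrocircuitDataset"))
  weighted <- isWeighted(d)
  lab <- graphLabels(d)
  out <- vector("list", 1L + nGraphs(d))
  out[[1L]] <- sprintf("%d %d", vertexCount(d), nGraphs(d))
  for (gi in seq_len(nGraphs(d))) {
    g <- members(d)[[gi]]
    hdr <- if (length(lab)) sprintf("graph %d %d", gi, lab[gi])
           else sprintf("graph %d", gi)
    e <- edges(g)
    body <- if (!nrow(e)) character(0)
      else if (weighted)
        sprintf("%d %d %s", e[, 1L], e[, 2L],
                formatC(edgeWeights(g), digits = 17, format = "g"))
      else sprintf("%d %d", e[, 1L], e[, 2L])
    out[[gi + 1L]] <- c(hdr, body)
  }
  writeLines(unlist(out), path, useBytes = TRUE)
  invisible(path)
}
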