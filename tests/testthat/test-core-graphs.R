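test_that("degree counts incident edges and validates the vertex index", {
  empty <- unweightedGraph(4)
  expect_identical(degree(empty, 3), 0L)

  path <- unweightedGraph(3, rbind(c(1, 2), c(2, 3)))
  expect_identical(degree(path, 2), 2L)

  single <- unweightedGraph(5, rbind(c(1, 2)))
  expect_identical(degree(single, 4), 0L)

  expect_error(degree(path, 0), "out of range")
  expect_error(degree(path, 4), "out of range")
})

test_that("graph constructors enforce simple-graph invariants", {
  expect_error(unweightedGraph(3, rbind(c(1, 1))), "self-loop")
  expect_error(unweightedGraph(3, rbind(c(1, 2), c(2, 1))), "duplicate")
  expect_error(unweightedGraph(3, rbind(c(1, 4))), "1..3")
  expect_error(microcircuit(3, rbind(c(1, 2)), numeric(0)),
               "one entry per edge")
  # normalization: orientation and listing order do not matter
  a <- unweightedGraph(4, rbind(c(3, 1), c(4, 2)))
  b <- unweightedGraph(4, rbind(c(2, 4), c(1, 3)))
  expect_identical(edges(a), edges(b))
  # weights follow their edges through normalization
  m <- microcircuit(4, rbind(c(3, 1), c(2, 4)), weights = c(0.9, 0.1))
  expect_equal(edgeWeights(m)[match(13, edges(m)[, 1] * 10 + edges(m)[, 2])],
               0.9)
})

test_that("sum of degrees equals twice the edge count", {
  for (s in 1:5) {
    g <- randomGraph(k = 12, ne = 5 * s, seed = s)
    expect_identical(sum(degree(g)), 2L * edgeCount(g))
  }
})

test_that("datasets validate the common vertex set and binary labels", {
  g5 <- unweightedGraph(5, rbind(c(1, 2)))
  g6 <- unweightedGraph(6, rbind(c(1, 2)))
  expect_error(microcircuitDataset(list(g5, g6)), "common vertex set")
  expect_error(microcircuitDataset(list(g5), labels = c(2L)), "binary")
  expect_error(microcircuitDataset(list(g5, g5), labels = 0L), "align")
  d <- microcircuitDataset(list(g5, g5), labels = c(0L, 1L))
  expect_identical(nGraphs(d), 2L)
  expect_identical(vertexCount(d), 5L)
})

test_that("a minimal file parses and malformed files name the bad line", {
  f <- withr::local_tempfile()
  writeLines(c("5 1", "graph 1", "1 2"), f)
  d <- readDataset(f)
  expect_identical(nGraphs(d), 1L)
  expect_identical(vertexCount(d), 5L)
  expect_identical(edgeCount(members(d)[[1]]), 1L)

  writeLines(c("5 1", "graph 1", "1 6"), f)
  expect_error(readDataset(f), ":3: .*outside 1\\.\\.5")

  writeLines(c("5 1", "graph 1", "1 2", "2 1"), f)
  expect_error(readDataset(f), "duplicate")

  writeLines(c("5 1", "graph 1", "1 2"), f)
  expect_error(readDataset(f, weighted = TRUE), ":3: .*3 fields")

  writeLines(c("5 1", "graph 1 7", "1 2"), f)
  expect_error(readDataset(f), "label must be 0 or 1")
})

test_that("write/read round-trips weighted datasets to 1e-12", {
  set.seed(42)
  mk <- function(seed) {
    set.seed(seed)
    microcircuit(6, rbind(c(1, 2), c(2, 5), c(3, 6)), weights = runif(3) * 2 - 1)
  }
  d <- microcircuitDataset(list(mk(1), mk(2), mk(3)), labels = c(0L, 1L, 0L))
  f <- withr::local_tempfile()
  writeDataset(d, f)
  d2 <- readDataset(f, weighted = TRUE)
  expect_identical(graphLabels(d2), graphLabels(d))
  for (i in 1:3) {
    expect_identical(edges(members(d2)[[i]]), edges(members(d)[[i]]))
    expect_equal(edgeWeights(members(d2)[[i]]), edgeWeights(members(d)[[i]]),
                 tolerance = 1e-12)
  }
  # read -> write -> read is a fixpoint on the serialized bytes
  f2 <- withr::local_tempfile()
  writeDataset(d2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("empty-edge graphs serialize as bare records", {
  d <- microcircuitDataset(list(unweightedGraph(4), unweightedGraph(4)))
  f <- withr::local_tempfile()
  writeDataset(d, f)
  expect_identical(readLines(f), c("4 2", "graph 1", "graph 2"))
  d2 <- readDataset(f)
  expect_identical(vapply(members(d2), edgeCount, integer(1)), c(0L, 0L))
})
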