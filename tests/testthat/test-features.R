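test_that("featureConcat is plain delimited concatenation", {
  expect_identical(featureConcat("27", "33", "_"), "27_33")
  expect_identical(featureConcat("a", "", "_"), "a_")
  expect_identical(featureConcat("x", "y", ","), "x,y")
})

test_that("hashFeature is the 32-hex lowercase MD5 digest", {
  # RFC 1321 reference vectors, frozen
  expect_identical(hashFeature(""), "d41d8cd98f00b204e9800998ecf8427e")
  expect_identical(hashFeature("abc"), "900150983cd24fb0d6963f7d28e17f72")
  expect_identical(hashFeature("message digest"),
                   "f96b697d7cb7938d525a2f31aaf161d0")
  set.seed(1)
  s <- replicate(20, paste(sample(c(letters, "_", 0:9), 12, TRUE),
                           collapse = ""))
  expect_true(all(grepl("^[0-9a-f]{32}$", hashFeature(s))))
  # cross-check against an independent MD5 implementation
  skip_if_not_installed("openssl")
  expect_identical(hashFeature(s),
                   vapply(s, function(x)
                     paste(as.character(openssl::md5(x)), collapse = ""),
                     character(1), USE.NAMES = FALSE))
  expect_identical(hashFeature(s), hashFeature(s))
})

test_that("a single edge produces the hand-traced library", {
  g <- unweightedGraph(2, rbind(c(1, 2)))
  lib <- extractFeatures(g, c("1", "2"), featureGenIters = 1)
  expect_identical(lib, c(hashFeature("E1"), "1", "2",
                          hashFeature("1_2"), hashFeature("2_1")))
})

test_that("degree-zero vertices use wrap-around sequence neighbors", {
  g <- unweightedGraph(3)
  lib <- extractFeatures(g, c("Z1", "Z2", "Z3"), featureGenIters = 1)
  # layout: edge-count feature, k initial labels, then k features per sweep
  expect_identical(lib[5:7], hashFeature(c("Z1_Z3_Z2", "Z2_Z1_Z3",
                                           "Z3_Z2_Z1")))
  # without the special rule a silent vertex is rehashed from itself
  lib2 <- extractFeatures(g, c("a", "b", "c"), 1, zeroDegreeSpecial = FALSE)
  expect_identical(lib2[5:7], hashFeature(c("a", "b", "c")))
})

test_that("library length is 1 + k + iters * k", {
  for (it in 1:3) for (s in 1:3) {
    g <- randomGraph(k = 9, ne = 3 * s, seed = s)
    expect_length(extractFeatures(g, initializeVertexLabels(g), it),
                  1 + 9 + it * 9)
  }
})

test_that("the library is invariant to edge listing order", {
  e <- rbind(c(1, 2), c(2, 3), c(4, 5), c(1, 5))
  set.seed(3)
  for (rep in 1:4) {
    perm <- sample(nrow(e))
    flip <- sample(c(TRUE, FALSE), nrow(e), TRUE)
    ee <- e[perm, ]
    ee[flip, ] <- ee[flip, 2:1]
    g1 <- unweightedGraph(5, e)
    g2 <- unweightedGraph(5, ee)
    expect_identical(extractFeatures(g1, initializeVertexLabels(g1), 2),
                     extractFeatures(g2, initializeVertexLabels(g2), 2))
  }
})

test_that("identity awareness separates isomorphic graphs on different IDs", {
  g34a <- unweightedGraph(5, rbind(c(1, 2)))
  g34b <- unweightedGraph(5, rbind(c(3, 4)))
  la <- extractFeatures(g34a, initializeVertexLabels(g34a), 2)
  lb <- extractFeatures(g34b, initializeVertexLabels(g34b), 2)
  expect_false(identical(la, lb))
  # hashed vertex features are entirely disjoint between the two
  expect_length(intersect(la[grepl("^[0-9a-f]{32}$", la)][-1],
                          lb[grepl("^[0-9a-f]{32}$", lb)][-1]), 0)
  # equal graphs produce identical libraries
  expect_identical(la, extractFeatures(g34a, initializeVertexLabels(g34a), 2))
})

test_that("relabeling matches an independent snapshot-semantics oracle", {
  for (s in 1:4) {
    g <- randomGraph(k = 8, ne = 4 + s, seed = 10 + s)
    init <- initializeVertexLabels(g)
    expect_identical(extractFeatures(g, init, 3), refLibrary(g, init, 3))
  }
  # and in plain (non-special) mode
  g <- randomGraph(k = 7, ne = 3, seed = 99)
  init <- initializeVertexLabels(g, "degree_only")
  expect_identical(extractFeatures(g, init, 2, zeroDegreeSpecial = FALSE),
                   refLibrary(g, init, 2, zeroDegreeSpecial = FALSE))
})

test_that("invalid extraction arguments are rejected", {
  g <- unweightedGraph(3, rbind(c(1, 2)))
  expect_error(extractFeatures(g, c("a", "b", "c"), 0), "positive")
  expect_error(extractFeatures(g, c("a", "b"), 1), "length")
})
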