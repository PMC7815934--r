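blobs <- function(n = 60, d = 4, sep = 5, sd = 0.1, seed = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * d, sd = sd), n, d) + outer(ifelse(y == 0, -sep, sep),
                                                   rep(1, d))
  list(x = x, y = y)
}

test_that("k-fold indices form a stratified partition", {
  y <- rep(c(0L, 1L), c(37, 63))
  sp <- kfoldIndices(y, folds = 10, seed = 4)
  tests <- lapply(sp, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:100)          # union is everything
  expect_identical(sum(duplicated(unlist(tests))), 0L)  # disjoint
  for (s in sp) {
    expect_identical(sort(c(s$train, s$test)), 1:100)
    expect_true(all(table(y[s$test]) >= 3))             # both classes present
  }
  expect_identical(kfoldIndices(y, 10, seed = 4), sp)   # seed reproducibility
  expect_false(identical(kfoldIndices(y, 10, seed = 5), sp))
  expect_error(kfoldIndices(rep(0L, 5), folds = 10), "fewer samples")
})

test_that("balanced accuracy averages per-class recalls", {
  expect_equal(balancedAccuracy(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(balancedAccuracy(c(0, 0, 1, 1), c(0, 0, 0, 0)), 0.5)
  expect_equal(balancedAccuracy(c(0, 0, 0, 1), c(0, 0, 1, 1)), 5 / 6)
  expect_error(balancedAccuracy(c(0, 0), c(0, 1)), "both classes")
})

test_that("all four classifiers separate well-separated blobs perfectly", {
  b <- blobs()
  ho <- 41:60  # held-out block spans both classes
  tr <- setdiff(1:60, ho)
  for (kind in c("single_mlp", "multi_mlp", "svm_rbf", "lda")) {
    sc <- fitAndScore(kind, b$x[tr, ], b$y[tr], b$x[ho, ], b$y[ho], seed = 1)
    expect_equal(unname(sc["test"]), 1, info = kind)
    expect_equal(unname(sc["train"]), 1, info = kind)
  }
  expect_error(fitAndScore("lda", b$x[1:10, ], rep(0L, 10),
                           b$x[ho, ], b$y[ho]), "single class")
})

test_that("shuffled labels score at chance", {
  b <- blobs(n = 200)
  set.seed(9)
  yShuf <- sample(b$y)
  res <- runExperiment(b$x, yShuf, classifiers = c("svm_rbf", "lda"),
                       folds = 10, seed = 7)
  # 3 sigma binomial band around 0.5 at n = 200
  expect_true(all(abs(res$meanTest - 0.5) < 3 * sqrt(0.25 / 200) + 0.05))
})

test_that("duplicated training rows leave SVM and LDA decisions unchanged", {
  b <- blobs(n = 40, sd = 1.5, sep = 0.8)  # overlapping classes
  ho <- c(11:20, 31:40)
  tr <- setdiff(1:40, ho)
  trDup <- c(tr, tr, tr)
  for (kind in c("svm_rbf", "lda")) {
    s1 <- fitAndScore(kind, b$x[tr, ], b$y[tr], b$x[ho, ], b$y[ho])
    s2 <- fitAndScore(kind, b$x[trDup, ], b$y[trDup], b$x[ho, ], b$y[ho])
    expect_equal(s1["test"], s2["test"], info = kind)
  }
})

test_that("paired t-tests flag undefined and significant cases correctly", {
  a <- c(0.9, 0.92, 0.91, 0.95, 0.9)
  expect_true(is.na(pairedTTest(a, a)$p))               # zero variance
  b <- a - 0.1 + rnorm(5, sd = 1e-6)
  out <- pairedTTest(a, b)
  expect_lt(out$p, 0.05)
  expect_true(out$significant)
  expect_equal(pairedTTest(a, b)$p, pairedTTest(b, a)$p) # symmetric
})

test_that("experiments re-run deterministically and export CSV", {
  b <- blobs()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  r1 <- runExperiment(b$x, b$y, classifiers = c("svm_rbf", "lda"),
                      folds = 5, seed = 11, outCsv = f1)
  r2 <- runExperiment(b$x, b$y, classifiers = c("svm_rbf", "lda"),
                      folds = 5, seed = 11, outCsv = f2)
  expect_identical(readLines(f1), readLines(f2))
  fs <- attr(r1, "foldScores")
  expect_identical(dim(fs$svm_rbf), c(5L, 2L))
})

test_that("t-SNE export writes one deterministic figure per channel", {
  b <- blobs(n = 40)
  chans <- list(b$x, b$x + 1)
  d1 <- withr::local_tempdir()
  out <- tsneChannels(chans, b$y, d1, seed = 3, perplexity = 10)
  expect_length(out, 2)
  expect_true(all(file.exists(out)))
  d2 <- withr::local_tempdir()
  out2 <- tsneChannels(chans, b$y, d2, seed = 3, perplexity = 10)
  expect_identical(readBin(out[1], "raw", 1e6), readBin(out2[1], "raw", 1e6))
  # well-separated classes stay separated in the 2-D projection
  coords <- attr(out, "coords")[[1]]
  expect_gt(silhouetteWidth(coords, b$y), 0.5)
})
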