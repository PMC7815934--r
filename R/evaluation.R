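#' Stratified k-fold cross-validation indices
#'
#' Randomly partitions \code{1..n} into \code{folds} disjoint test sets
#' whose union is all indices; by default the split is stratified by label
#' so every fold carries both classes (unstratified splits of imbalanced
#' data can produce single-class training folds).
#'
#' @param labels binary label vector (used for stratification and to define
#'   \code{n}).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param stratify logical (default \code{TRUE}).
#' @return list of \code{folds} elements, each \code{list(train, test)}.
#' @export
kfoldIndices <- function(labels, folds = 10L, seed = 1L, stratify = TRUE) {
  n <- length(labels)
  folds <- as.integer(folds)
  if (n < folds) stop("fewer samples than folds")
  .withSeed(seed, {
    assignFold <- integer(n)
    groups <- if (stratify) split(seq_len(n), labels) else list(seq_len(n))
    for (g in groups) {
      g <- sample(g)
      assignFold[g] <- rep_len(seq_len(folds), length(g))
    }
    lapply(seq_len(folds), function(f)
      list(train = which(assignFold != f), test = which(assignFold == f)))
  })
}

#' Balanced accuracy
#'
#' The mean of the per-class recalls of a binary prediction; the accuracy
#' measure of choice for imbalanced label distributions.
#'
#' @param yTrue true 0/1 labels (both classes must occur).
#' @param yPred predicted 0/1 labels.
#' @return value in \code{[0, 1]}.
#' @examples
#' balancedAccuracy(c(0, 0, 0, 1), c(0, 0, 1, 1))  # (2/3 + 1)/2
#' @export
balancedAccuracy <- function(yTrue, yPred) {
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  stopifnot(length(yTrue) == length(yPred))
  if (length(unique(yTrue)) < 2L)
    stop("both classes must be present in yTrue")
  r0 <- mean(yPred[yTrue == 0L] == 0L)
  r1 <- mean(yPred[yTrue == 1L] == 1L)
  (r0 + r1) / 2
}

#' Train one classifier and score it
#'
#' Fits one of the four downstream classifiers and returns train/test
#' scores.  The classifiers, with hyperparameters held fixed across all
#' experiments:
#' \itemize{
#'   \item \code{single_mlp}: one hidden layer of 128 ReLU units, 2-unit
#'     softmax output, Adam, 100 epochs (mini-batches of 32);
#'   \item \code{multi_mlp}: hidden layers of 128 and 64 ReLU units,
#'     otherwise identical;
#'   \item \code{svm_rbf}: RBF-kernel SVM with \code{C = 100},
#'     \code{gamma = 0.1} (via \pkg{e1071});
#'   \item \code{lda}: linear discriminant analysis with
#'     \code{tol = 1e-4} (via \pkg{MASS}).
#' }
#'
#' Features are standardized per column (center/scale estimated on the
#' training fold only) before fitting, so that the fixed classifier
#' hyperparameters see comparably scaled inputs regardless of the embedding
#' that produced them.
#'
#' @param kind one of \code{"single_mlp"}, \code{"multi_mlp"},
#'   \code{"svm_rbf"}, \code{"lda"}.
#' @param xTrain,yTrain,xTest,yTest training/test features and 0/1 labels.
#' @param seed seed for the MLP initialisation and batching.
#' @param scoring \code{"accuracy"} or \code{"balanced"}.
#' @param standardize logical; z-score features using training-fold
#'   statistics (default \code{TRUE}).
#' @return named numeric vector \code{c(train = ..., test = ...)}.
#' @export
fitAndScore <- function(kind, xTrain, yTrain, xTest, yTest, seed = 1L,
                        scoring = c("accuracy", "balanced"),
                        standardize = TRUE) {
  scoring <- match.arg(scoring)
  kind <- match.arg(kind, c("single_mlp", "multi_mlp", "svm_rbf", "lda"))
  yTrain <- as.integer(yTrain); yTest <- as.integer(yTest)
  xTrain <- as.matrix(xTrain); xTest <- as.matrix(xTest)
  if (standardize) {
    mu <- colMeans(xTrain)
    sdv <- apply(xTrain, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    xTrain <- scale(xTrain, mu, sdv)
    xTest <- scale(xTest, mu, sdv)
  }
  if (length(unique(yTrain)) < 2L)
    stop("training fold contains a single class; use stratified folds")
  predictor <- switch(kind,
    single_mlp = {
      mod <- .mlpTrain(xTrain, yTrain, hidden = 128L, seed = seed)
      function(X) .mlpPredict(mod, X)
    },
    multi_mlp = {
      mod <- .mlpTrain(xTrain, yTrain, hidden = c(128L, 64L), seed = seed)
      function(X) .mlpPredict(mod, X)
    },
    svm_rbf = {
      mod <- e1071::svm(x = as.matrix(xTrain), y = factor(yTrain,
                        levels = c(0L, 1L)), kernel = "radial",
                        cost = 100, gamma = 0.1, scale = FALSE)
      function(X) as.integer(as.character(predict(mod, as.matrix(X))))
    },
    lda = {
      mod <- MASS::lda(as.matrix(xTrain), grouping = factor(yTrain,
                       levels = c(0L, 1L)), tol = 1e-4)
      function(X)
        as.integer(as.character(predict(mod, as.matrix(X))$class))
    })
  score <- function(yTrue, yPred)
    if (scoring == "balanced") balancedAccuracy(yTrue, yPred)
    else mean(yTrue == yPred)
  c(train = score(yTrain, predictor(xTrain)),
    test = score(yTest, predictor(xTest)))
}

#' Paired two-tailed t-test on fold scores
#'
#' @param scoresA,scoresB equal-length score vectors (>= 2), paired by fold.
#' @return list with \code{p} (two-tailed p-value; \code{NA} when all
#'   pairwise differences are equal, where the test is undefined),
#'   \code{significant} (at 0.05) and \code{meanDiff}.
#' @export
pairedTTest <- function(scoresA, scoresB) {
  stopifnot(length(scoresA) == length(scoresB), length(scoresA) >= 2L)
  d <- scoresA - scoresB
  if (stats::sd(d) == 0)
    return(list(p = NA_real_, significant = NA, meanDiff = mean(d)))
  ht <- stats::t.test(scoresA, scoresB, paired = TRUE,
                      alternative = "two.sided")
  list(p = ht$p.value, significant = ht$p.value < 0.05,
       meanDiff = mean(d))
}

#' Cross-validated evaluation of an embedding
#'
#' Runs stratified k-fold cross-validation of one or more downstream
#' classifiers on a precomputed embedding matrix, reporting per-classifier
#' mean and standard deviation of train and test scores in the
#' "mean +/- std" convention.
#'
#' @param embedding numeric matrix, one row per graph.
#' @param labels 0/1 labels aligned with rows.
#' @param classifiers character vector of classifier kinds (see
#'   [fitAndScore()]).
#' @param folds number of CV folds (default 10).
#' @param seed seed for the fold split and the MLPs.
#' @param scoring \code{"accuracy"} or \code{"balanced"}.
#' @param outCsv optional path; when given, the result table is also
#'   written as CSV.
#' @return data.frame with one row per classifier (columns
#'   \code{classifier}, \code{meanTest}, \code{sdTest}, \code{meanTrain},
#'   \code{sdTrain}); the raw per-fold scores are attached as attribute
#'   \code{"foldScores"} (a named list of \code{folds x 2} matrices).
#' @export
runExperiment <- function(embedding, labels,
                          classifiers = c("single_mlp", "multi_mlp",
                                          "svm_rbf", "lda"),
                          folds = 10L, seed = 1L,
                          scoring = c("accuracy", "balanced"),
                          outCsv = NULL) {
  scoring <- match.arg(scoring)
  embedding <- as.matrix(embedding)
  labels <- as.integer(labels)
  stopifnot(nrow(embedding) == length(labels))
  splits <- kfoldIndices(labels, folds = folds, seed = seed)
  foldScores <- lapply(classifiers, function(kind) {
    sc <- vapply(seq_along(splits), function(f) {
      sp <- splits[[f]]
      fitAndScore(kind, embedding[sp$train, , drop = FALSE],
                  labels[sp$train],
                  embedding[sp$test, , drop = FALSE], labels[sp$test],
                  seed = seed + f, scoring = scoring)
    }, numeric(2))
    t(sc)  # folds x (train, test)
  })
  names(foldScores) <- classifiers
  res <- data.frame(
    classifier = classifiers,
    meanTest = vapply(foldScores, function(s) mean(s[, "test"]), numeric(1)),
    sdTest = vapply(foldScores, function(s) stats::sd(s[, "test"]), numeric(1)),
    meanTrain = vapply(foldScores, function(s) mean(s[, "train"]), numeric(1)),
    sdTrain = vapply(foldScores, function(s) stats::sd(s[, "train"]), numeric(1)),
    row.names = NULL)
  attr(res, "foldScores") <- foldScores
  if (!is.null(outCsv)) write.csv(res, outCsv, row.names = FALSE)
  res
}

#' Per-channel t-SNE scatter plots
#'
#' Projects each channel's embedding matrix to two dimensions with t-SNE
#' and writes one PNG scatter per channel, colored by binary label.  Useful
#' for eyeballing which channels separate the classes.
#'
#' @param channelEmbeddings list of numeric matrices (one per channel), as
#'   returned by [wgeviaChannels()].
#' @param labels 0/1 labels aligned with rows.
#' @param outDir output directory (created if missing).
#' @param seed t-SNE seed.
#' @param perplexity t-SNE perplexity; reduced automatically when the
#'   sample count is too small for the default.
#' @return invisible character vector of written file paths, with the list
#'   of 2-D coordinate matrices attached as attribute \code{"coords"}.
#' @export
tsneChannels <- function(channelEmbeddings, labels, outDir, seed = 1L,
                         perplexity = 30) {
  stopifnot(is.list(channelEmbeddings), length(channelEmbeddings) >= 1L)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  labels <- as.integer(labels)
  paths <- character(length(channelEmbeddings))
  coordList <- vector("list", length(channelEmbeddings))
  for (j in seq_along(channelEmbeddings)) {
    X <- as.matrix(channelEmbeddings[[j]])
    n <- nrow(X)
    perp <- min(perplexity, floor((n - 1) / 3))
    coords <- .withSeed(seed + j,
      Rtsne::Rtsne(X, dims = 2, perplexity = max(perp, 1),
                   check_duplicates = FALSE, pca = FALSE,
                   max_iter = 500)$Y)
    paths[j] <- file.path(outDir, sprintf("channel_%02d.png", j))
    grDevices::png(paths[j], width = 600, height = 600)
    plot(coords, col = ifelse(labels == 0L, "steelblue", "sienna"),
         pch = 19, cex = 0.6, xlab = "t-SNE 1", ylab = "t-SNE 2",
         main = sprintf("Channel %d", j))
    grDevices::dev.off()
    coordList[[j]] <- coords
  }
  attr(paths, "coords") <- coordList
  invisible(paths)
}
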