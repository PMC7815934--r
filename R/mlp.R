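# Small dense multilayer perceptron for binary classification: ReLU hidden
# layers, 2-unit softmax output, cross-entropy loss, Adam, mini-batches.
# Written in base matrix ops; the embedding dimensions involved (<= 80) make
# this entirely CPU-friendly.

.mlpTrain <- function(X, y, hidden = c(128L), epochs = 100L, batch = 32L,
                      lr = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(X) == length(y))
  sizes <- c(ncol(X), hidden, 2L)
  L <- length(sizes) - 1L
  .withSeed(seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    n <- nrow(X)
    Y <- cbind(1 - y, y)  # one-hot

    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        a <- list(X[idx, , drop = FALSE])
        # forward
        for (l in seq_len(L)) {
          z <- sweep(a[[l]] %*% W[[l]], 2L, b[[l]], "+")
          a[[l + 1L]] <- if (l < L) pmax(z, 0) else z
        }
        z <- a[[L + 1L]]
        z <- z - apply(z, 1L, max)
        p <- exp(z); p <- p / rowSums(p)
        # backward
        delta <- (p - Y[idx, , drop = FALSE]) / length(idx)
        step <- step + 1L
        for (l in rev(seq_len(L))) {
          gW <- crossprod(a[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          corr1 <- 1 - beta1^step; corr2 <- 1 - beta2^step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) /
            (sqrt(vW[[l]] / corr2) + eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) /
            (sqrt(vb[[l]] / corr2) + eps)
        }
      }
    }
    structure(list(W = W, b = b, sizes = sizes), class = "wgeviaMlp")
  })
}

.mlpPredict <- function(model, X) {
  a <- as.matrix(X)
  L <- length(model$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% model$W[[l]], 2L, model$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  as.integer(max.col(a) == 2L)
}
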