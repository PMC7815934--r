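noInput <- function(duration = 100, seed = 1, sigma = 0, n = 4) {
  list(cfg = simulationConfig(nA = n / 2, nB = n / 2, stimRate = 0,
                              duration = duration, seed = seed),
       par = neuronParams(sigma = sigma))
}

test_that("the resting potential is a fixed point of the noiseless dynamics", {
  s <- noInput()
  tr <- simulateCondition(s$cfg, s$par)
  expect_true(all(potentials(tr) == 0))
  expect_identical(sum(spikes(tr)), 0L)
})

test_that("noiseless decay from rho0 matches the closed form within Euler error", {
  s <- noInput(duration = 60)
  tr <- simulateCondition(s$cfg, s$par, rho0 = 0.5)
  rho <- potentials(tr)[1, ]
  tau <- s$par$tau
  # after one membrane time constant the gap to rest shrinks by e^-1
  expect_equal(rho[tau] / 0.5, exp(-1), tolerance = 0.03)
  # full trajectory tracks exp(-t/tau) at first order in dt/tau
  expect_equal(rho, 0.5 * (1 - 1 / tau)^seq_along(rho), tolerance = 1e-12)
  expect_lt(max(abs(rho - 0.5 * exp(-seq_along(rho) / tau))), 0.01)
})

test_that("spearmanCorr agrees with rank arithmetic", {
  x <- c(1, 3, 7, 9)
  expect_equal(spearmanCorr(x, x^2), 1)          # monotone transform
  expect_equal(spearmanCorr(x, rev(x)), -1)
  expect_equal(spearmanCorr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  # oracle equivalence on all 4! rank permutations
  perms <- wgevia:::.permutations(4)
  for (p in perms)
    expect_equal(spearmanCorr(1:4, as.numeric(p)),
                 refSpearmanNoTies(1:4, as.numeric(p)))
  expect_warning(out <- spearmanCorr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
  expect_error(spearmanCorr(1:3, 1:4), "equal length")
  expect_error(spearmanCorr(1:2, 1:2), ">= 3")
})

test_that("windowed microcircuits cover full windows with weights in [-1, 1]", {
  cfg <- simulationConfig(nA = 5, nB = 5, duration = 85, window = 40, seed = 3)
  tr <- simulateCondition(cfg)
  d <- buildMicrocircuits(tr, 40)
  expect_identical(nGraphs(d), 2L)  # trailing 5 frames dropped
  w <- unlist(lapply(members(d), edgeWeights))
  expect_true(all(w >= -1 & w <= 1))
  expect_identical(edgeCount(members(d)[[1]]), 45L)  # complete graph on 10
  expect_error(buildMicrocircuits(tr, 100), "longer than trace")
  # determinism: identical trace segments give identical microcircuits
  tr2 <- new("ActivityTrace",
             potentials = cbind(potentials(tr)[, 1:40],
                                potentials(tr)[, 1:40]),
             spikes = cbind(spikes(tr)[, 1:40], spikes(tr)[, 1:40]))
  d2 <- buildMicrocircuits(tr2, 40)
  expect_identical(edgeWeights(members(d2)[[1]]), edgeWeights(members(d2)[[2]]))
})

test_that("independent noise pairs have near-zero windowed correlation", {
  # tau = 1 makes the membrane noise white; slower membranes (tau = 20)
  # autocorrelate the traces and widen the finite-window Spearman null
  cfg <- simulationConfig(nA = 10, nB = 10, stimRate = 0, duration = 40,
                          seed = 5)
  tr <- simulateCondition(cfg, neuronParams(sigma = 0.5, tau = 1,
                                            spikeThreshold = 1e6))
  d <- buildMicrocircuits(tr, 40)
  w <- edgeWeights(members(d)[[1]])
  expect_gt(mean(abs(w) < 0.3), 0.9)
})

test_that("labeled two-condition datasets assemble reproducibly", {
  cfg <- simulationConfig(nA = 10, nB = 10, window = 20, seed = 17)
  d <- generateSimuDataset(3, 4, cfg)
  expect_identical(nGraphs(d), 7L)
  expect_identical(graphLabels(d), c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  d2 <- generateSimuDataset(3, 4, cfg)
  expect_identical(lapply(members(d), edgeWeights),
                   lapply(members(d2), edgeWeights))
})

test_that("parent multiplicity shapes the coupling structure between groups", {
  # 1-2 parents concentrate the drive into few strong pairwise couplings;
  # 3-4 parents dilute it across more, weaker partners
  strong <- t(sapply(1:6, function(s) sapply(1:2, function(cond) {
    tr <- simulateCondition(simulationConfig(condition = cond,
                                             duration = 400, seed = 200 + s))
    p <- potentials(tr)
    R <- suppressWarnings(cor(t(p), method = "spearman"))
    sum(R[1:50, 51:100] > 0.3, na.rm = TRUE)
  })))
  expect_true(all(strong[, 1] > strong[, 2]))
})
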