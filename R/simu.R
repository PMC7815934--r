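#' Integrate-and-fire neuron parameters
#'
#' Leaky integrate-and-fire dynamics with additive noise,
#' \deqn{d\rho/dt = (\rho_{rest} - \rho)/\tau + \sigma \tau^{-1/2} \epsilon,}
#' where \eqn{\epsilon} is standard Gaussian noise.  A neuron spikes when
#' \eqn{\rho} exceeds \code{spikeThreshold}, is reset to \code{rhoRest} and
#' stays silent for \code{refractory} time units.
#'
#' @param rhoRest resting potential (potential units; default 0).
#' @param tau membrane time constant (time units; default 20).
#' @param sigma noise scale (default 0.05).
#' @param spikeThreshold spiking threshold (default 1).
#' @param refractory silent period after a spike (time units; default 2).
#' @param dt Euler integration step (default 1; one step = one frame).
#' @return a validated list of class \code{"NeuronParams"}.
#' @export
neuronParams <- function(rhoRest = 0, tau = 20, sigma = 0.05,
                         spikeThreshold = 1, refractory = 2, dt = 1) {
  p <- list(rhoRest = rhoRest, tau = tau, sigma = sigma,
            spikeThreshold = spikeThreshold, refractory = refractory,
            dt = dt)
  if (!all(vapply(p, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all neuron parameters must be finite numbers")
  stopifnot(p$tau > 0, p$dt > 0, p$refractory >= 0, p$sigma >= 0)
  class(p) <- "NeuronParams"
  p
}

#' Two-group network simulation configuration
#'
#' A network of \code{nA + nB} neurons.  Group A neurons have no parents and
#' are driven by independent Poisson stimulus events; each group B neuron is
#' activated by a fixed set of parent neurons drawn from group A -- 1 or 2
#' parents under condition 1, 3 or 4 under condition 2.  Every parent spike
#' delivers a synaptic increment to the child's membrane potential.
#'
#' @param nA,nB group sizes (defaults 50 and 50).
#' @param condition 1 or 2.
#' @param stimRate per-step probability of a stimulus event at each group A
#'   neuron (default 0.05).
#' @param stimAmplitude potential increment per stimulus event (default 1.5,
#'   suprathreshold so stimulated neurons spike reliably).
#' @param synapticWeight potential increment per parent spike (default 0.4).
#' @param duration number of frames to simulate.
#' @param window frames per Spearman correlation window (default 40).
#' @param seed integer seed.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nA = 50L, nB = 50L, condition = 1L,
                             stimRate = 0.05, stimAmplitude = 1.5,
                             synapticWeight = 0.4, duration = 4000L,
                             window = 40L, seed = 1L) {
  cfg <- list(nA = as.integer(nA), nB = as.integer(nB),
              condition = as.integer(condition), stimRate = stimRate,
              stimAmplitude = stimAmplitude,
              synapticWeight = synapticWeight,
              duration = as.integer(duration), window = as.integer(window),
              seed = as.integer(seed))
  stopifnot(cfg$nA >= 1L, cfg$nB >= 1L, cfg$condition %in% c(1L, 2L),
            cfg$duration >= 1L, cfg$window >= 3L,
            cfg$stimRate >= 0, cfg$stimRate <= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate one experimental condition
#'
#' Euler-integrates the noisy leaky integrate-and-fire dynamics for all
#' neurons.  Parent sets for group B are drawn once per simulation: 1-2
#' parents per neuron under condition 1, 3-4 under condition 2.  Stimulus
#' events and noise are drawn from R's RNG, so results are reproducible for
#' a fixed \code{cfg$seed}.  During the refractory period a neuron holds its
#' resting potential and ignores input.
#'
#' @param cfg a [simulationConfig()].
#' @param params a [neuronParams()].
#' @param rho0 initial membrane potential, recycled across neurons (default
#'   the resting potential).
#' @return an [ActivityTrace-class]; group A neurons occupy rows
#'   \code{1..nA}, group B rows \code{nA+1..nA+nB}.  The parent assignment
#'   is attached as attribute \code{"parents"}.
#' @export
simulateCondition <- function(cfg = simulationConfig(),
                              params = neuronParams(),
                              rho0 = params$rhoRest) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(params, "NeuronParams"), all(is.finite(rho0)))
  n <- cfg$nA + cfg$nB
  tf <- cfg$duration
  .withSeed(cfg$seed, {
    parentChoices <- if (cfg$condition == 1L) 1:2 else 3:4
    parents <- lapply(seq_len(cfg$nB), function(i)
      sample.int(cfg$nA, sample(parentChoices, 1L)))

    dt <- params$dt
    leak <- dt / params$tau
    noiseScale <- params$sigma / sqrt(params$tau) * dt
    refSteps <- ceiling(params$refractory / dt)

    rho <- rep_len(rho0, n)
    refLeft <- integer(n)
    pot <- matrix(0, n, tf)
    spk <- matrix(0L, n, tf)
    aIdx <- seq_len(cfg$nA)
    bIdx <- cfg$nA + seq_len(cfg$nB)
    # parent-child incidence: child i receives synapticWeight per parent spike
    parentMat <- matrix(0, cfg$nB, cfg$nA)
    for (i in seq_len(cfg$nB)) parentMat[i, parents[[i]]] <- 1

    for (t in seq_len(tf)) {
      active <- refLeft == 0L
      drho <- (params$rhoRest - rho) * leak + noiseScale * rnorm(n)
      # group A first: Poisson stimulus events, possible spike this frame
      stim <- runif(cfg$nA) < cfg$stimRate * dt
      rhoA <- ifelse(active[aIdx],
                     rho[aIdx] + drho[aIdx] + stim * cfg$stimAmplitude,
                     params$rhoRest)
      firedA <- active[aIdx] & rhoA > params$spikeThreshold
      # group B: synaptic input arrives within the parent's spike frame
      synInput <- cfg$synapticWeight * as.numeric(parentMat %*% firedA)
      rhoB <- ifelse(active[bIdx], rho[bIdx] + drho[bIdx] + synInput,
                     params$rhoRest)
      firedB <- active[bIdx] & rhoB > params$spikeThreshold
      rho <- c(rhoA, rhoB)
      fired <- c(firedA, firedB)
      # record the pre-reset potential so spikes are visible in the trace
      pot[, t] <- rho
      spk[fired, t] <- 1L
      rho[fired] <- params$rhoRest
      refLeft[fired] <- refSteps
      cooling <- !fired & !active
      refLeft[cooling] <- refLeft[cooling] - 1L
    }
    trace <- new("ActivityTrace", potentials = pot, spikes = spk)
    attr(trace, "parents") <- parents
    trace
  })
}

#' Spearman rank correlation of two series
#'
#' Rank correlation with average ranks for ties.  Constant series have
#' undefined rank correlation; \code{NA} is returned with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \code{[-1, 1]}, or \code{NA} for constant input.
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("series must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant series: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Build windowed microcircuits from activity traces
#'
#' Splits the trace into non-overlapping windows of \code{window} frames
#' (trailing frames beyond the last full window are dropped) and builds one
#' complete weighted microcircuit per window, with the edge weight of every
#' neuron pair equal to the Spearman correlation of their activity within
#' the window.  Pairs whose correlation is undefined (a constant series,
#' e.g. a silent neuron) get weight 0.  No pre-thresholding is applied; the
#' multi-channel embedder performs all thresholding.
#'
#' @param trace an [ActivityTrace-class].
#' @param window frames per window (>= 3, <= number of frames).
#' @param use \code{"potentials"} (default) or \code{"spikes"}: which series
#'   to correlate.
#' @return an unlabeled [MicrocircuitDataset-class] with one member per
#'   window.
#' @export
buildMicrocircuits <- function(trace, window, use = c("potentials", "spikes")) {
  stopifnot(is(trace, "ActivityTrace"))
  use <- match.arg(use)
  vals <- if (use == "potentials") potentials(trace)
          else { s <- spikes(trace); storage.mode(s) <- "double"; s }
  window <- as.integer(window)
  tf <- ncol(vals)
  if (window < 3L) stop("window must be >= 3 frames")
  if (window > tf) stop("window longer than trace")
  nWin <- tf %/% window
  k <- nrow(vals)
  up <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  em <- cbind(up[, 1L], up[, 2L])
  membersList <- vector("list", nWin)
  for (wI in seq_len(nWin)) {
    seg <- vals[, ((wI - 1L) * window + 1L):(wI * window), drop = FALSE]
    R <- suppressWarnings(stats::cor(t(seg), method = "spearman"))
    w <- R[upper.tri(R)]
    w[!is.finite(w)] <- 0
    membersList[[wI]] <- microcircuit(k, em, w)
  }
  microcircuitDataset(membersList)
}

#' Generate a labeled two-condition simulated microcircuit dataset
#'
#' Runs the integrate-and-fire simulation once per condition -- condition 1
#' (group B neurons with 1-2 parents, label 0) long enough for \code{n0}
#' windows and condition 2 (3-4 parents, label 1) for \code{n1} windows --
#' and concatenates the windowed microcircuits with their condition labels.
#'
#' @param n0,n1 number of graphs (windows) for conditions 1 and 2.
#' @param cfg template [simulationConfig()]; condition, duration and seed
#'   are overridden per condition (sub-seeds \code{seed} and
#'   \code{seed + 1000003}).
#' @param params a [neuronParams()].
#' @param use series to correlate, see [buildMicrocircuits()].
#' @return a labeled weighted [MicrocircuitDataset-class] with
#'   \code{n0 + n1} members.
#' @export
generateSimuDataset <- function(n0, n1, cfg = simulationConfig(),
                                params = neuronParams(),
                                use = "potentials") {
  n0 <- as.integer(n0); n1 <- as.integer(n1)
  stopifnot(n0 >= 1L, n1 >= 1L)
  one <- function(cond, nWin, seed) {
    c2 <- cfg
    c2$condition <- cond
    c2$duration <- nWin * cfg$window
    c2$seed <- seed
    buildMicrocircuits(simulateCondition(c2, params), cfg$window, use = use)
  }
  d0 <- one(1L, n0, cfg$seed)
  d1 <- one(2L, n1, cfg$seed + 1000003L)
  microcircuitDataset(c(members(d0), members(d1)),
                      labels = c(rep(0L, n0), rep(1L, n1)))
}
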