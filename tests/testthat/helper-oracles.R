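# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive, direct implementations (double loops, exhaustive
# enumeration, straight-from-formula evaluation) so they share no code with
# the implementation paths they check.

# Gaussian-smoothed central-difference derivative, scalar double loop,
# reflective boundaries
naiveSmoothDeriv <- function(x, sigmaSamples, dt) {
  T <- length(x)
  xs <- x
  if (sigmaSamples > 0) {
    rad <- max(1L, ceiling(4 * sigmaSamples))
    k <- exp(-0.5 * ((-rad):rad / sigmaSamples)^2)
    k <- k / sum(k)
    reflect <- function(i) {
      while (i < 1 || i > T) {
        if (i < 1) i <- 2 - i
        if (i > T) i <- 2 * T - i
      }
      i
    }
    xs <- numeric(T)
    for (t in seq_len(T)) {
      s <- 0
      for (o in -rad:rad) s <- s + k[o + rad + 1] * x[reflect(t + o)]
      xs[t] <- s
    }
  }
  d <- numeric(T)
  for (t in 2:(T - 1)) d[t] <- (xs[t + 1] - xs[t - 1]) / (2 * dt)
  d[1] <- (xs[2] - xs[1]) / dt
  d[T] <- (xs[T] - xs[T - 1]) / dt
  d
}

# CP reconstruction by explicit triple loop over outer products
naiveCPReconstruct <- function(lambda, U1, U2, U3) {
  out <- array(0, c(nrow(U1), nrow(U2), nrow(U3)))
  for (r in seq_along(lambda))
    for (i in seq_len(nrow(U1)))
      for (j in seq_len(nrow(U2)))
        for (k in seq_len(nrow(U3)))
          out[i, j, k] <- out[i, j, k] + lambda[r] * U1[i, r] * U2[j, r] * U3[k, r]
  out
}

# weighted-SBM description length straight from the formulas, in plain R
dlOracle <- function(W, labels) {
  lab <- as.integer(factor(labels))
  B <- max(lab)
  n <- nrow(W)
  nb <- tabulate(lab, B)
  L <- log(n) + lchoose(n - 1, B - 1) + lgamma(n + 1) - sum(lgamma(nb + 1))
  for (r in seq_len(B)) for (s in r:B) {
    sub <- W[lab == r, lab == s, drop = FALSE]
    ylogs <- -log(sub[sub > 0])  # Beta(theta,1) sufficient statistic
    if (r == s) {
      N <- nb[r] * (nb[r] - 1) / 2
      e <- sum(sub > 0) / 2
      sw <- sum(ylogs) / 2
    } else {
      N <- nb[r] * nb[s]
      e <- sum(sub > 0)
      sw <- sum(ylogs)
    }
    if (N > 0)
      L <- L + log(N + 1) + lchoose(N, e) + (e + 1) * log1p(sw) - lgamma(e + 1)
  }
  L
}

# all set partitions of n elements as restricted-growth strings (0-based)
setPartitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in 0:(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(0L, 0L)
  out
}

# planted-block weighted graph: B equal blocks, Bernoulli densities
# pin/pout, Beta weights with means win/wout
plantedBlockGraph <- function(n, B, pin, pout, win, wout, conc = 10, seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(B), length.out = n)[order(runif(n))]
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same <- lab[i] == lab[j]
    if (runif(1) < (if (same) pin else pout)) {
      mu <- if (same) win else wout
      A[i, j] <- A[j, i] <- max(rbeta(1, mu * conc, (1 - mu) * conc), 1e-12)
    }
  }
  rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
  list(A = A, labels = setNames(lab - 1L, rownames(A)))
}

# random weighted graph with loose structure (for oracle-equivalence tests)
randomWeightedGraph <- function(n, seed) {
  set.seed(seed)
  if (seed %% 2 == 0) {
    B <- sample(2:3, 1)
    g <- plantedBlockGraph(n, B, 0.8, 0.25, 0.7, 0.25, conc = 6, seed = seed + 1000)
    return(g$A)
  }
  A <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (runif(1) < 0.5) A[i, j] <- A[j, i] <- runif(1, 0.05, 1)
  rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
  A
}

# exhaustive minimum-description-length partition of a small graph
exhaustiveBestPartition <- function(graph) {
  n <- igraph::vcount(graph)
  parts <- setPartitions(n)
  dls <- vapply(parts, function(p) descriptionLength(graph, p), 0)
  list(dl = min(dls), labels = parts[[which.min(dls)]], all = dls, parts = parts)
}

# convenience: the canonical two-circuit study condition; windows scale with
# the time axis (for T = 400: samples [61, 141) and [221, 301))
twoCircuitSpec <- function(seed, noiseSd = 0.05, nNeurons = 24, nAnimals = 5,
                           nTimepoints = 400) {
  w <- function(a, b) c(floor(a * nTimepoints) + 1L, floor(b * nTimepoints) + 1L)
  circuits <- list(plantedCircuit(1:min(5, nNeurons - 1), w(0.15, 0.35)))
  if (nNeurons >= 10)
    circuits <- c(circuits, list(plantedCircuit(6:10, w(0.55, 0.75))))
  simSpec(nNeurons, nAnimals, nTimepoints, circuits,
          noiseSd = noiseSd, seed = seed)
}
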