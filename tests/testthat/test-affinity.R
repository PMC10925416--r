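makeTraces <- function(mat, dt = 0.25) {
  # single-animal TraceSet from a neurons x time matrix
  new("TraceSet", activity = array(mat, c(1, nrow(mat), ncol(mat))),
      neuronIds = paste0("n", seq_len(nrow(mat))),
      animalIds = "w1", observed = matrix(TRUE, 1, nrow(mat)), dt = dt)
}

test_that("smoothed derivative is exact on constants and lines", {
  T <- 60
  tt <- (seq_len(T) - 1) * 0.25
  tr <- makeTraces(rbind(rep(2.5, T), 3 * tt))
  d <- smoothDerivative(tr, sigma = 0)
  expect_true(all(d@d[1, 1, ] == 0))
  expect_lt(max(abs(d@d[1, 2, 2:(T - 1)] - 3)), 1e-9 * 3)
  expect_error(smoothDerivative(makeTraces(matrix(1:4, 2, 2))), "3 time points")
})

test_that("smoothed derivative matches the naive convolution oracle", {
  T <- 80; dt <- 0.25
  tt <- (seq_len(T) - 1) * dt
  x1 <- sin(2 * pi * tt / 7)
  x2 <- exp(-tt / 5) + 0.3 * cos(tt)
  tr <- makeTraces(rbind(x1, x2), dt)
  for (sigma in c(0.5, 1)) {
    d <- smoothDerivative(tr, sigma = sigma)
    expect_lt(max(abs(d@d[1, 1, ] - naiveSmoothDeriv(x1, sigma / dt, dt))), 1e-10)
    expect_lt(max(abs(d@d[1, 2, ] - naiveSmoothDeriv(x2, sigma / dt, dt))), 1e-10)
  }
})

test_that("derivative is linear in the traces", {
  T <- 50; dt <- 0.25
  set.seed(42)
  x <- rnorm(T); y <- rnorm(T)
  dx <- smoothDerivative(makeTraces(rbind(x, y, x + y), dt), sigma = 1)
  expect_equal(dx@d[1, 1, ] + dx@d[1, 2, ], dx@d[1, 3, ], tolerance = 1e-12)
})

test_that("monotone segments follow the sign runs of the derivative", {
  T <- 100; dt <- 0.25
  tt <- (seq_len(T) - 1) * dt
  tr <- makeTraces(rbind(tt, rep(0, T)), dt)
  d <- smoothDerivative(tr, sigma = 0)
  segs <- monotoneSegments(d, zeroBand = 1e-9, minDuration = 3 * dt)
  tab <- segmentTable(segs, 1, 1)
  expect_equal(nrow(tab), 1)        # a rising ramp is one "+" segment
  expect_equal(tab$sign, 1)
  expect_gte(tab$start, 1); expect_lte(tab$start, 2)
  expect_equal(segmentTable(segs, 1, 2)$sign, integer(0))  # flat: no segment

  # triangle wave: boundaries at the apex samples +/- 1 sample, matching a
  # direct run-length oracle on the sign sequence
  x <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1],
         seq(0, 1, length.out = 26)[-1], rep(1, 25))[1:T]
  tr2 <- makeTraces(rbind(x, x), dt)
  d2 <- smoothDerivative(tr2, sigma = 0)
  segs2 <- monotoneSegments(d2, zeroBand = 1e-9, minDuration = 3 * dt)
  tab2 <- segmentTable(segs2, 1, 1)
  sgn <- ifelse(abs(d2@d[1, 1, ]) <= 1e-9, 0L, ifelse(d2@d[1, 1, ] > 0, 1L, -1L))
  r <- rle(sgn)
  oracleStarts <- (cumsum(r$lengths) - r$lengths + 1L)[r$values != 0 & r$lengths >= 3]
  expect_equal(tab2$sign, c(1, -1, 1))
  expect_lte(max(abs(tab2$start - oracleStarts)), 1)
})

test_that("an all-subthreshold derivative yields no segments", {
  T <- 50
  set.seed(9)
  tr <- makeTraces(rbind(rnorm(T, sd = 1e-4), rnorm(T, sd = 1e-4)), 0.25)
  d <- smoothDerivative(tr, sigma = 0.5)
  segs <- monotoneSegments(d, zeroBand = 1, minDuration = 0.75)
  expect_true(all(segs@signs == 0L))
  a <- differentialAffinity(d, segs, kappa = 1)
  expect_true(all(affinityValues(a) == 0))
})

test_that("differential affinity follows the min/max ratio with magnitude gate", {
  T <- 100; dt <- 0.25
  tt <- (seq_len(T) - 1) * dt
  # slopes 1 and 2, near-disabled gate: affinity ~= 0.5 at interior points
  tr <- makeTraces(rbind(tt, 2 * tt, rep(1, T)), dt)
  d <- smoothDerivative(tr, sigma = 0)
  segs <- monotoneSegments(d, zeroBand = 1e-9, minDuration = 3 * dt)
  a <- differentialAffinity(d, segs, kappa = 1e-9)
  v <- affinityValues(a)
  pm <- pairMap(a)
  p12 <- which(pm[, 1] == 1 & pm[, 2] == 2)
  p13 <- which(pm[, 1] == 1 & pm[, 2] == 3)
  expect_equal(unname(v[1, p12, 5:(T - 5)]), rep(0.5, T - 9), tolerance = 1e-9)
  expect_true(all(v[1, p13, ] == 0))   # constant partner: no shared segment
  # explicit gate: slopes equal, kappa = slope -> a = 1 - exp(-1)
  a2 <- differentialAffinity(d, segs, kappa = 2)
  expect_equal(unname(affinityValues(a2)[1, p12, 10]), 0.5 * (1 - exp(-2 / 2)),
               tolerance = 1e-12)
})

test_that("affinity is invariant under sign flips of either trace", {
  T <- 120; dt <- 0.25
  set.seed(7)
  x <- cumsum(rnorm(T)); y <- cumsum(rnorm(T))
  base <- makeTraces(rbind(x, y), dt)
  flip <- makeTraces(rbind(x, -y), dt)
  both <- makeTraces(rbind(-x, -y), dt)
  val <- function(tr) {
    d <- smoothDerivative(tr, sigma = 1)
    segs <- monotoneSegments(d, zeroBand = 0.05, minDuration = 0.75)
    affinityValues(differentialAffinity(d, segs, kappa = 0.5))
  }
  expect_identical(val(base), val(flip))
  expect_identical(val(base), val(both))
})

test_that("affinity is scale-covariant when kappa is rescaled", {
  T <- 90; dt <- 0.25
  set.seed(12)
  x <- cumsum(rnorm(T)); y <- cumsum(rnorm(T))
  c0 <- 3.7
  v1 <- local({
    d <- smoothDerivative(makeTraces(rbind(x, y), dt), sigma = 1)
    segs <- monotoneSegments(d, zeroBand = 0.1, minDuration = 0.75)
    affinityValues(differentialAffinity(d, segs, kappa = 0.4))
  })
  v2 <- local({
    d <- smoothDerivative(makeTraces(c0 * rbind(x, y), dt), sigma = 1)
    segs <- monotoneSegments(d, zeroBand = c0 * 0.1, minDuration = 0.75)
    affinityValues(differentialAffinity(d, segs, kappa = c0 * 0.4))
  })
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("affinities are bounded and time-reversal preserves their multiset", {
  T <- 80; dt <- 0.25
  set.seed(5)
  x <- cumsum(rnorm(T)); y <- cumsum(rnorm(T))
  val <- function(m) {
    d <- smoothDerivative(makeTraces(m, dt), sigma = 1)
    segs <- monotoneSegments(d, zeroBand = 0.05, minDuration = 0.75)
    affinityValues(differentialAffinity(d, segs, kappa = 0.5))
  }
  v <- val(rbind(x, y))
  expect_true(all(v >= 0 & v <= 1))
  vr <- val(rbind(rev(x), rev(y)))
  expect_equal(sort(as.numeric(vr)), sort(as.numeric(v)), tolerance = 1e-12)
})

test_that("bundleMatrix produces a symmetric, zero-diagonal slice with NA for missing", {
  spec <- twoCircuitSpec(3, nNeurons = 6, nAnimals = 2, nTimepoints = 60)
  spec$circuits <- list(plantedCircuit(1:3, c(11, 51)))
  traces <- simulateTraces(spec)$traces
  traces@observed[2, 5] <- FALSE
  aff <- affinitySeries(traces)
  A <- bundleMatrix(aff, 30, 1)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_equal(vectorizeMatrix(A), unname(affinityValues(aff)[1, , 30]))
  A2 <- bundleMatrix(aff, 30, 2)
  expect_true(all(is.na(A2[5, -5])) && all(is.na(A2[-5, 5])))
  expect_true(!anyNA(A2[-5, -5]))
})
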