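test_that("pair indexing is the lexicographic bijection over i < j", {
  pm <- pairIndex(3)
  expect_equal(unname(pm), cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)))
  expect_error(pairIndex(1), "n >= 2")
  # n = 4: pair (2,4) sits at position 5 (1-based lexicographic order)
  expect_equal(pairToIndex(2L, 4L, 4L), 5L)
  for (n in c(2, 5, 17, 50)) {
    pm <- pairIndex(n)
    expect_equal(nrow(pm), n * (n - 1) / 2)
    expect_equal(pairToIndex(pm[, 1], pm[, 2], n), seq_len(nrow(pm)))
  }
})

test_that("vectorize and factorToMatrix are mutually inverse", {
  set.seed(1)
  for (n in c(3, 6, 11)) {
    A <- matrix(0, n, n)
    v0 <- runif(n * (n - 1) / 2)
    A <- factorToMatrix(v0, ids = paste0("x", seq_len(n)))
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_equal(unname(vectorizeMatrix(A)), v0)
  }
  expect_error(factorToMatrix(runif(4)), "n\\(n-1\\)/2")
  expect_error(factorToMatrix(runif(3), ids = c("a", "b")), "length")
})

test_that("the affinity tensor matches bundled slices and masks missing pairs", {
  spec <- twoCircuitSpec(2, nNeurons = 5, nAnimals = 2, nTimepoints = 40)
  spec$circuits <- list(plantedCircuit(1:3, c(6, 36)))
  traces <- simulateTraces(spec)$traces
  traces@observed[2, 4] <- FALSE
  aff <- affinitySeries(traces)
  tens <- buildTensor(aff)
  expect_equal(dim(tensorData(tens)), c(40, 2, 10))
  for (t in c(1, 17, 40))
    expect_equal(tensorData(tens)[t, 1, ],
                 unname(vectorizeMatrix(bundleMatrix(aff, t, 1))))
  # one unobserved neuron masks exactly n-1 pair columns for that animal
  m <- tensorMask(tens)
  expect_true(all(m[, 1, ]))
  badPairs <- which(!m[1, 2, ])
  expect_equal(sort(rowSums(pairMap(tens)[badPairs, , drop = FALSE] == 4) > 0),
               rep(TRUE, 4))
  expect_equal(length(badPairs), 4)
})

test_that("cpReconstruct agrees with the naive triple-loop oracle", {
  set.seed(4)
  for (rep in 1:3) {
    U1 <- matrix(runif(6 * 2), 6, 2); U2 <- matrix(runif(3 * 2), 3, 2)
    U3 <- matrix(runif(5 * 2), 5, 2); lambda <- runif(2, 0.5, 2)
    got <- cpReconstruct(list(lambda = lambda, temporal = U1, animal = U2,
                              affinity = U3))
    expect_equal(got, naiveCPReconstruct(lambda, U1, U2, U3), tolerance = 1e-12)
  }
  # one-hot factors: a single non-zero entry equal to lambda
  e <- function(n, i) { v <- matrix(0, n, 1); v[i, 1] <- 1; v }
  got <- cpReconstruct(list(lambda = 2.5, temporal = e(4, 2), animal = e(3, 1),
                            affinity = e(6, 5)))
  expect_equal(sum(got != 0), 1)
  expect_equal(got[2, 1, 5], 2.5)
})

test_that("HALS handles zero tensors and recovers exact low-rank structure", {
  z <- halsFit(array(0, c(4, 3, 5)), rank = 2, nRestarts = 2, seed = 1)
  expect_equal(z@objective, 0)
  expect_true(all(lambdas(z) == 0))

  set.seed(2)
  U1 <- matrix(runif(12), 12, 1); U2 <- matrix(runif(4), 4, 1)
  U3 <- matrix(runif(8), 8, 1)
  X <- cpReconstruct(list(lambda = 1, temporal = U1, animal = U2, affinity = U3))
  fit <- halsFit(X, rank = 1, nRestarts = 3, seed = 1)
  relErr <- sqrt(2 * fit@objective) / sqrt(sum(X^2))
  expect_lte(relErr, 1e-8)
  expect_true(all(diff(objectiveHistory(fit)) <= 1e-10))
  # canonical form: unit-norm factors, scale in lambda
  f <- factorMatrices(fit)
  for (M in f) expect_equal(sqrt(colSums(M^2)), 1, ignore_attr = TRUE)
  expect_warning(halsFit(X, rank = 6, nRestarts = 1, seed = 1, maxIter = 5),
                 "rank exceeds")
})

test_that("masked entries never influence the fit", {
  set.seed(3)
  X <- cpReconstruct(list(lambda = c(2, 1),
                          temporal = matrix(runif(20), 10, 2),
                          animal = matrix(runif(8), 4, 2),
                          affinity = matrix(runif(12), 6, 2)))
  mask <- array(runif(length(X)) > 0.2, dim(X))
  mk <- function(data) new("AffinityTensor", data = data, mask = mask,
                           pairs = pairIndex(4), neuronIds = paste0("n", 1:4),
                           animalIds = paste0("w", 1:4), dt = 1)
  X2 <- X
  X2[!mask] <- 77  # garbage in masked cells
  f1 <- halsFit(mk(X), rank = 2, nRestarts = 2, seed = 5)
  f2 <- halsFit(mk(X2), rank = 2, nRestarts = 2, seed = 5)
  expect_identical(factorMatrices(f1), factorMatrices(f2))
  expect_identical(objectiveHistory(f1), objectiveHistory(f2))
})

test_that("rank diagnostics favor the planted rank and nest objectives", {
  set.seed(6)
  planted <- list(lambda = c(3, 2, 1),
                  temporal = matrix(runif(30), 10, 3),
                  animal = matrix(runif(18), 6, 3),
                  affinity = matrix(runif(45), 15, 3))
  X <- cpReconstruct(planted)
  diag1 <- selectRank(X, ranks = 1, nRestarts = 2, seed = 1)
  expect_equal(nrow(diag1), 1)
  diags <- selectRank(X, ranks = c(1, 2, 3, 4), nRestarts = 3, seed = 1)
  expect_true(all(diff(diags$bestObjective) <= 1e-8))
})

test_that("restart stability peaks at the planted rank, not at overfit ranks", {
  wins <- 0
  for (b in 1:3) {
    set.seed(300 + b)
    planted <- list(lambda = c(3, 2, 1),
                    temporal = matrix(runif(36), 12, 3),
                    animal = matrix(runif(18), 6, 3),
                    affinity = matrix(runif(60), 20, 3))
    X <- cpReconstruct(planted) + array(rnorm(12 * 6 * 20, 0, 0.01), c(12, 6, 20))
    X[X < 0] <- 0
    di <- selectRank(X, ranks = c(3, 6), nRestarts = 4, seed = 100 * b)
    if (di$stability[1] > di$stability[2]) wins <- wins + 1
  }
  expect_gte(wins, 2)
})
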