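test_that("graphFromMatrix thresholds entries and keeps isolated nodes", {
  n <- 5
  A <- matrix(0.4, n, n); diag(A) <- 0
  g <- graphFromMatrix(A, wMin = 1e-12)
  expect_equal(igraph::ecount(g), n * (n - 1) / 2)
  expect_equal(igraph::vcount(g), n)
  g0 <- graphFromMatrix(A, wMin = 0.9)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), n)
  # block matrix: two 3-node blocks at .9, cross-block .05, threshold .1
  B <- matrix(0.05, 6, 6)
  B[1:3, 1:3] <- 0.9; B[4:6, 4:6] <- 0.9; diag(B) <- 0
  gb <- graphFromMatrix(B, wMin = 0.1)
  expect_equal(igraph::ecount(gb), 6)
  Abad <- A; Abad[1, 2] <- 0.7; Abad[2, 1] <- 0.1
  expect_error(graphFromMatrix(Abad), "symmetric")
  Abig <- A; Abig[1, 2] <- Abig[2, 1] <- 1.7
  expect_error(graphFromMatrix(Abig), "rescale")
})

test_that("description length matches the straight-from-formula oracle everywhere", {
  # exhaustive: every one of the 203 partitions of a 6-node graph
  A <- randomWeightedGraph(6, seed = 31)
  g <- graphFromMatrix(A)
  W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  parts <- setPartitions(6)
  expect_length(parts, 203)
  for (p in parts)
    expect_equal(descriptionLength(g, p), dlOracle(W, p), tolerance = 1e-9)
  # and on a larger random graph with random labelings
  A2 <- randomWeightedGraph(12, seed = 8)
  g2 <- graphFromMatrix(A2)
  set.seed(99)
  for (rep in 1:10) {
    lab <- sample(0:3, 12, replace = TRUE)
    expect_equal(descriptionLength(g2, lab), dlOracle(A2, lab), tolerance = 1e-9)
  }
})

test_that("description length is label-permutation invariant and prefers planted splits", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 0.9; A[5:8, 5:8] <- 0.9; diag(A) <- 0
  g <- graphFromMatrix(A)
  planted <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_identical(descriptionLength(g, planted),
                   descriptionLength(g, 1 - planted))
  expect_identical(descriptionLength(g, planted),
                   descriptionLength(g, c(5, 5, 5, 5, 2, 2, 2, 2)))
  expect_lt(descriptionLength(g, planted), descriptionLength(g, rep(0, 8)))
})

test_that("MCMC recovers unambiguous two-clique structure for every seed", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 0.9; A[5:8, 5:8] <- 0.9; diag(A) <- 0
  g <- graphFromMatrix(A)
  planted <- c(rep(0L, 4), rep(1L, 4))
  for (s in 1:10) {
    part <- mcmcPartition(g, seed = s, burnin = 30, sampling = 50, anneal = 30)
    expect_equal(nmi(membershipLabels(part), planted), 1)
  }
})

test_that("MCMC is deterministic given a seed and bookkeeping matches recomputation", {
  A <- randomWeightedGraph(10, seed = 4)
  g <- graphFromMatrix(A)
  p1 <- mcmcPartition(g, seed = 3, burnin = 50, sampling = 100, anneal = 50,
                      checkIncremental = TRUE)
  p2 <- mcmcPartition(g, seed = 3, burnin = 50, sampling = 100, anneal = 50,
                      checkIncremental = TRUE)
  expect_identical(membershipLabels(p1), membershipLabels(p2))
  expect_identical(p1@dl, p2@dl)
  expect_identical(p1@dlTrace, p2@dlTrace)
  expect_lte(p1@incrMaxErr, 1e-9)
  # model averaging: per-node marginal label distributions sum to 1
  expect_equal(unname(rowSums(p1@marginals)), rep(1, 10), tolerance = 1e-12)
  # the reported dl is exactly the dl of the reported labeling
  expect_equal(p1@dl, descriptionLength(g, membershipLabels(p1)), tolerance = 1e-12)
})

test_that("MCMC attains the exhaustive-enumeration optimum on small graphs", {
  hits <- 0
  for (s in 1:6) {
    A <- randomWeightedGraph(6 + (s %% 2), seed = 40 + s)
    g <- graphFromMatrix(A)
    best <- exhaustiveBestPartition(g)
    part <- mcmcPartition(g, seed = s, burnin = 50, sampling = 100, anneal = 50)
    expect_gte(part@dl, best$dl - 1e-9)  # never better than the global optimum
    if (abs(part@dl - best$dl) <= 1e-9) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("weight-shuffled nulls do not inflate the inferred community count", {
  wins <- 0
  for (s in 1:10) {
    pg <- plantedBlockGraph(36, 3, 0.9, 0.15, 0.8, 0.15, seed = 700 + s)
    g <- graphFromMatrix(pg$A)
    set.seed(s)
    w <- igraph::E(g)$weight
    gShuf <- igraph::set_edge_attr(g, "weight", value = sample(w))
    cStruct <- max(membershipLabels(
      mcmcPartition(g, seed = s, burnin = 50, sampling = 100, anneal = 50))) + 1L
    cShuf <- max(membershipLabels(
      mcmcPartition(gShuf, seed = s, burnin = 50, sampling = 100, anneal = 50))) + 1L
    if (cShuf <= cStruct) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("community reports revert components to members, windows and traces", {
  spec <- twoCircuitSpec(21)
  sim <- simulateTraces(spec)
  aff <- affinitySeries(sim$traces)
  model <- halsFit(buildTensor(aff), 2, nRestarts = 2, seed = 1, maxIter = 150)
  fa <- factorMatrices(model)$affinity[, 1]
  g <- graphFromMatrix(factorToMatrix(fa / max(fa), ids = neuronIds(sim$traces)))
  part <- mcmcPartition(g, seed = 1, burnin = 50, sampling = 100, anneal = 50)
  rep1 <- communityReport(g, part, model, 1L, sim$traces)
  expect_equal(sum(rep1$communities$size), 24)
  # planted data: the circuit community is internally heavy, externally light
  circ <- rep1$communities[which.max(rep1$communities$intraWeight), ]
  expect_gte(circ$intraWeight, 5 * circ$interWeight)
  # the reported window must match one planted circuit window
  ft <- factorMatrices(model)$temporal[, 1]
  wins <- list(c(61, 141), c(221, 301))
  whichCirc <- which.max(c(cor(ft, as.numeric(seq_len(400) %in% 61:140)),
                           cor(ft, as.numeric(seq_len(400) %in% 221:300))))
  expect_gte(rep1$window[1], wins[[whichCirc]][1] - 12)
  expect_lte(rep1$window[2], wins[[whichCirc]][2] + 12)
  # the community holding the circuit members is exactly the planted set
  members <- strsplit(rep1$communities$members, ",")
  planted <- neuronIds(sim$traces)[sim$truth$circuits[[whichCirc]]$members]
  found <- members[[which.max(vapply(members, function(m) length(intersect(m, planted)), 0))]]
  expect_setequal(found, planted)
  # snippets cover the window for the top-loading animals
  expect_length(rep1$topAnimals, 3)
  sn <- rep1$snippets[[1]][[1]]
  expect_equal(ncol(sn), rep1$window[2] - rep1$window[1])
  expect_error(communityReport(g, setNames(rep(0L, 24), paste0("zz", 1:24)),
                               model, 1L, sim$traces), "do not match")
})

test_that("a one-hot temporal factor pins the reported window to its spike", {
  g <- graphFromMatrix(factorToMatrix(rep(0.5, 3), ids = paste0("n", 1:3)))
  part <- mcmcPartition(g, seed = 1, burnin = 10, sampling = 20, anneal = 10)
  ft <- matrix(0, 50, 1); ft[37, 1] <- 1
  model <- list(temporal = ft, animal = matrix(1, 2, 1),
                affinity = matrix(rep(0.5, 3), 3, 1))
  mockModel <- new("CPModel", rank = 1L, lambda = 1, temporal = ft,
                   animal = matrix(1, 2, 1), affinity = matrix(0.5, 3, 1),
                   objective = 0, objHistory = 0, seed = 1L, iterations = 1L,
                   converged = TRUE, pairs = pairIndex(3),
                   neuronIds = paste0("n", 1:3), animalIds = c("w1", "w2"))
  rep1 <- communityReport(g, part, mockModel, 1L)
  expect_true(rep1$window[1] <= 37 && 37 < rep1$window[2])
})
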