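test_that("NMI matches hand-computed contingency values and igraph's oracle", {
  expect_identical(nmi(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_identical(nmi(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)      # relabeling
  expect_identical(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)      # independent table
  # MI = ln 2, entropies (ln 2, 1.5 ln 2): arithmetic-mean NMI = 0.8 exactly
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 2)), 0.8, tolerance = 1e-12)
  expect_identical(nmi(rep(0, 5), rep(3, 5)), 1)              # both single-cluster
  expect_identical(nmi(rep(0, 5), c(0, 0, 1, 1, 2)), 0)       # one single-cluster
  expect_error(nmi(c(0, 1), c(0, 1, 2)), "length")
  set.seed(10)
  for (rep in 1:8) {
    p <- sample(0:3, 30, replace = TRUE)
    q <- sample(0:2, 30, replace = TRUE)
    expect_equal(nmi(p, q), nmi(q, p), tolerance = 1e-12)     # symmetry
    expect_equal(nmi(p, q), igraph::compare(p + 1, q + 1, method = "nmi"),
                 tolerance = 1e-12)                           # independent oracle
  }
})

test_that("LFR specs are validated before any sampling happens", {
  expect_error(lfrSpec(minComm = 70, n = 60), "maxComm")
  expect_error(lfrSpec(minComm = 30, maxComm = 20), "minComm")
  expect_error(lfrSpec(muTopo = 1.2), "muTopo")
  expect_error(lfrSpec(tau1 = 0.5), "tau1")
  expect_error(lfrSpec(avgDeg = 25, maxDeg = 20), "avgDeg")
})

test_that("LFR networks honor mixing, weight bounds and simplicity", {
  # muTopo = 0: all edges internal
  net0 <- lfrGenerate(lfrSpec(n = 60, muTopo = 0, seed = 5))
  expect_equal(net0$realizedMu, 0)
  el <- igraph::as_edgelist(net0$graph, names = FALSE)
  expect_true(all(net0$planted[el[, 1]] == net0$planted[el[, 2]]))

  net <- lfrGenerate(lfrSpec(n = 100, muTopo = 0.3, seed = 2))
  w <- igraph::E(net$graph)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_false(igraph::any_multiple(net$graph))
  expect_false(any(igraph::which_loop(net$graph)))
  expect_true(all(table(net$planted) >= 2))
  expect_equal(sum(net$sizes), 100)

  # realized inter-community fraction tracks muTopo (10-seed average)
  mus <- vapply(1:10, function(s)
    lfrGenerate(lfrSpec(n = 500, muTopo = 0.3, maxDeg = 30, seed = s))$realizedMu, 0)
  expect_lt(abs(mean(mus) - 0.3), 0.05)
})

test_that("within-community weights exceed between-community weights when muW < 0.5", {
  net <- lfrGenerate(lfrSpec(n = 120, muTopo = 0.4, muW = 0.2, seed = 7))
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  w <- igraph::E(net$graph)$weight
  within <- net$planted[el[, 1]] == net$planted[el[, 2]]
  expect_gt(mean(w[within]), mean(w[!within]))
  expect_lt(abs(mean(w[within]) - 0.8), 0.1)
  expect_lt(abs(mean(w[!within]) - 0.2), 0.1)
})

test_that("greedy modularity resolves cliques and degenerate graphs", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 0.8; A[5:8, 5:8] <- 0.8; diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("v", 1:8)
  lab <- greedyModularity(graphFromMatrix(A))
  expect_equal(nmi(lab, c(rep(0, 4), rep(1, 4))), 1)
  # complete uniform graph: no split beats Q = 0, single community returned
  K <- matrix(0.5, 6, 6); diag(K) <- 0
  labK <- greedyModularity(graphFromMatrix(K))
  expect_equal(max(labK), 0)
  # edgeless graph: singletons
  E0 <- matrix(0, 4, 4)
  expect_equal(unname(greedyModularity(graphFromMatrix(E0))), 0:3)
})

test_that("greedy modularity reaches the exhaustive optimum on separable graphs", {
  # graphs with clear-cut planted structure, where greedy agglomeration
  # provably lands on the modularity optimum found by brute force
  for (s in 1:3) {
    pg <- plantedBlockGraph(7, 2, 1.0, 0.1, 0.9, 0.1, seed = 50 + s)
    g <- graphFromMatrix(pg$A)
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    lab <- greedyModularity(g)
    qOf <- function(p) igraph::modularity(g, p + 1, weights = igraph::E(g)$weight)
    qAll <- vapply(setPartitions(7), qOf, 0)
    expect_gte(qOf(unname(lab)), max(qAll) - 1e-9)
  }
})

test_that("runBenchmark aggregates seeded instances into a stable table", {
  specs <- list(lfrSpec(n = 40, muTopo = 0.1, minComm = 8, maxComm = 14,
                        maxDeg = 12, avgDeg = 6))
  ctl <- list(burnin = 30, sampling = 60, anneal = 30)
  b1 <- runBenchmark(specs, methods = c("greedy"), nReps = 2, seed = 9)
  expect_equal(nrow(b1$table), 1)
  expect_equal(b1$table$nOk, 2)
  expect_equal(b1$table$meanNMI, mean(b1$scores[1, 1, ]))
  b2 <- runBenchmark(specs, methods = c("sbm", "greedy"), nReps = 2, seed = 9,
                     mcmcControl = ctl)
  b3 <- runBenchmark(specs, methods = c("sbm", "greedy"), nReps = 2, seed = 9,
                     mcmcControl = ctl)
  expect_identical(b2$table, b3$table)   # fixed master seed: identical rerun
  expect_identical(b2$scores, b3$scores)
  # a failing external method is recorded as missing, not dropped
  boom <- function(graph) stop("no partition for you")
  b4 <- runBenchmark(specs, methods = list(greedy = "greedy", ext = boom),
                     nReps = 2, seed = 9)
  expect_equal(b4$table$nOk[b4$table$method == "ext"], 0)
  expect_true(is.nan(b4$table$meanNMI[b4$table$method == "ext"]))
  # external partitions can come from files through the adapter
  dir <- withr::local_tempdir()
  adapter <- function(graph) {
    path <- file.path(dir, "ext.json")
    writePartition(setNames(rep(0L, igraph::vcount(graph)),
                            igraph::V(graph)$name), path)
    readPartition(path)
  }
  b5 <- runBenchmark(specs, methods = list(ext = adapter), nReps = 1, seed = 9)
  expect_equal(b5$table$nOk, 1)
})

test_that("mean NMI does not improve as topological mixing grows", {
  # 5-seed means across muTopo in {0.1, 0.3, 0.5}; allow one inversion
  means <- vapply(c(0.1, 0.3, 0.5), function(mu) {
    b <- runBenchmark(list(lfrSpec(n = 50, muTopo = mu, avgDeg = 6,
                                   maxDeg = 15, minComm = 10, maxComm = 18)),
                      methods = "greedy", nReps = 5, seed = 4)
    b$table$meanNMI
  }, 0)
  expect_lte(sum(diff(means) > 0.02), 1)
})
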