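#' Specify a weighted benchmark network (LFR-style)
#'
#' Planted-community benchmark in the Lancichinetti-Fortunato-Radicchi
#' style: power-law degrees and community sizes, a topological mixing
#' fraction `muTopo` (share of each node's edges leaving its community) and
#' a weight mixing parameter `muW` (within-community edges draw weights with
#' mean `1 - muW`, between-community edges with mean `muW`; both Beta
#' distributed on (0, 1) with concentration `weightConc`).
#'
#' @param n nodes.
#' @param tau1 degree power-law exponent (> 1).
#' @param tau2 community-size power-law exponent (> 1).
#' @param muTopo topological mixing fraction in [0, 1].
#' @param muW weight mixing parameter in [0, 1].
#' @param avgDeg,maxDeg target average and maximum degree.
#' @param minComm,maxComm community-size bounds.
#' @param weightConc Beta concentration of the weight distributions.
#' @param seed RNG seed.
#' @return an `lfrSpec` list (validated for feasibility).
#' @export
lfrSpec <- function(n = 60, tau1 = 2.5, tau2 = 1.5, muTopo = 0.3, muW = 0.3,
                    avgDeg = 8, maxDeg = 20, minComm = 8, maxComm = 20,
                    weightConc = 20, seed = 1L) {
  stopifnot2(tau1 > 1 && tau2 > 1, "tau1 and tau2 must exceed 1")
  stopifnot2(muTopo >= 0 && muTopo <= 1, "muTopo must lie in [0, 1]")
  stopifnot2(muW >= 0 && muW <= 1, "muW must lie in [0, 1]")
  stopifnot2(minComm <= maxComm, "minComm must not exceed maxComm")
  stopifnot2(maxComm <= n, "maxComm cannot exceed n")
  stopifnot2(minComm >= 2, "communities need at least 2 nodes")
  stopifnot2(avgDeg >= 1 && avgDeg <= maxDeg, "need 1 <= avgDeg <= maxDeg")
  stopifnot2(maxDeg < n, "maxDeg must be below n")
  structure(list(n = as.integer(n), tau1 = tau1, tau2 = tau2, muTopo = muTopo,
                 muW = muW, avgDeg = avgDeg, maxDeg = maxDeg,
                 minComm = as.integer(minComm), maxComm = as.integer(maxComm),
                 weightConc = weightConc, seed = as.integer(seed)),
            class = "lfrSpec")
}

# sample from a continuous truncated Pareto with exponent tau on [kmin, kmax]
rpareto <- function(m, tau, kmin, kmax) {
  u <- runif(m)
  a <- tau - 1
  lo <- kmin^(-a); hi <- kmax^(-a)
  (lo - u * (lo - hi))^(-1 / a)
}

# choose kmin so the truncated Pareto mean matches the target
paretoKmin <- function(avg, tau, kmax) {
  a <- tau - 1
  if (abs(a - 1) < 1e-9) a <- a + 1e-6  # avoid the removable singularity
  f <- function(kmin)
    (a / (a - 1)) * (kmin^(1 - a) - kmax^(1 - a)) /
      (kmin^(-a) - kmax^(-a)) - avg
  lo <- 1; hi <- kmax - 1e-6
  if (f(hi) < 0) return(hi)
  if (f(lo) > 0) return(lo)
  stats::uniroot(f, c(lo, hi))$root
}

# pair stubs randomly, rejecting forbidden partners; returns an edge matrix
pairStubs <- function(stubs, forbid, maxTries = 100L) {
  edges <- matrix(integer(0), 0, 2)
  pool <- sample(stubs)
  have <- new.env(hash = TRUE)
  while (length(pool) >= 2L) {
    u <- pool[1]
    pool <- pool[-1]
    placed <- FALSE
    for (try in seq_len(min(maxTries, length(pool)))) {
      k <- sample.int(length(pool), 1L)
      v <- pool[k]
      key <- paste(min(u, v), max(u, v))
      if (v != u && !forbid(u, v) && is.null(have[[key]])) {
        edges <- rbind(edges, c(u, v))
        have[[key]] <- TRUE
        pool <- pool[-k]
        placed <- TRUE
        break
      }
    }
    # unplaceable stub dropped (degree sequence honored approximately)
  }
  edges
}

#' Generate a weighted benchmark network with planted communities
#'
#' Degrees are drawn from a truncated power law matched to `avgDeg`,
#' community sizes from a power law on [minComm, maxComm]; each node splits
#' its degree into an internal part (fraction `1 - muTopo`, wired inside its
#' community by a rejection-based configuration model) and an external part
#' (wired across communities, same scheme). Within-community weights have
#' mean `1 - muW`, between-community weights mean `muW` (Beta on (0, 1)).
#'
#' @param spec an [lfrSpec()].
#' @return list (class `benchmarkNetwork`): `graph` (weighted igraph),
#'   `planted` (named 0-based integer labels), `spec`, `realizedMu`
#'   (realized inter-community edge fraction), `sizes` (community sizes).
#' @export
lfrGenerate <- function(spec) {
  stopifnot2(inherits(spec, "lfrSpec"), "spec must come from lfrSpec()")
  set.seed(spec$seed)
  n <- spec$n
  kmin <- paretoKmin(spec$avgDeg, spec$tau1, spec$maxDeg)
  deg <- pmin(pmax(round(rpareto(n, spec$tau1, kmin, spec$maxDeg)), 1L), spec$maxDeg)
  # community sizes: power law until they cover n, last one trimmed/merged
  sizes <- integer(0)
  while (sum(sizes) < n) {
    s <- round(rpareto(1, spec$tau2, spec$minComm, spec$maxComm))
    sizes <- c(sizes, min(max(s, spec$minComm), spec$maxComm))
  }
  excess <- sum(sizes) - n
  if (excess > 0) {
    last <- sizes[length(sizes)] - excess
    if (last >= spec$minComm) sizes[length(sizes)] <- last
    else {
      sizes <- sizes[-length(sizes)]
      short <- n - sum(sizes)
      sizes[seq_len(short)] <- sizes[seq_len(short)] + 1L  # spread remainder
    }
  }
  C <- length(sizes)
  # assign nodes (largest internal degree first) to communities with room
  dint <- round((1 - spec$muTopo) * deg)
  dint <- pmin(dint, deg)
  comm <- integer(n)
  room <- sizes
  for (i in order(-dint)) {
    fits <- which(room > 0 & (sizes - 1L) >= dint[i])
    pick <- if (length(fits)) fits[sample.int(length(fits), 1L)]
            else which.max(room)
    comm[i] <- pick
    room[pick] <- room[pick] - 1L
  }
  dint <- pmin(dint, sizes[comm] - 1L)  # cap by community capacity
  dext <- deg - dint
  # wire internal stubs within each community
  edges <- matrix(integer(0), 0, 2)
  for (cc in seq_len(C)) {
    nodes <- which(comm == cc)
    stubs <- rep(nodes, dint[nodes])
    if (length(stubs) %% 2L == 1L) stubs <- stubs[-which.max(dint[stubs])]
    if (length(stubs) >= 2L)
      edges <- rbind(edges, pairStubs(stubs, function(u, v) FALSE))
  }
  intraCount <- nrow(edges)
  # wire external stubs across communities
  stubs <- rep(seq_len(n), dext)
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-1]
  if (length(stubs) >= 2L) {
    seen <- new.env(hash = TRUE)
    for (r in seq_len(nrow(edges))) {
      key <- paste(min(edges[r, ]), max(edges[r, ]))
      seen[[key]] <- TRUE
    }
    ext <- pairStubs(stubs, function(u, v)
      comm[u] == comm[v] || !is.null(seen[[paste(min(u, v), max(u, v))]]))
    edges <- rbind(edges, ext)
  }
  interCount <- nrow(edges) - intraCount
  # weights: Beta means 1-muW within, muW between, clipped away from 0
  within <- comm[edges[, 1]] == comm[edges[, 2]]
  betaDraw <- function(m, mu) {
    mu <- min(max(mu, 0.01), 0.99)
    pmax(rbeta(m, mu * spec$weightConc, (1 - mu) * spec$weightConc), 1e-12)
  }
  w <- numeric(nrow(edges))
  w[within] <- betaDraw(sum(within), 1 - spec$muW)
  w[!within] <- betaDraw(sum(!within), spec$muW)
  ids <- paste0("v", seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(edges))
    g <- igraph::add_edges(g, t(edges), weight = w)
  structure(list(graph = g,
                 planted = setNames(as.integer(comm - 1L), ids),
                 spec = spec,
                 realizedMu = if (nrow(edges)) interCount / nrow(edges) else 0,
                 sizes = sizes),
            class = "benchmarkNetwork")
}

#' Normalized mutual information between two labelings
#'
#' Plug-in mutual information of the contingency table, normalized by the
#' arithmetic mean of the two label entropies (0 ln 0 := 0). Returns 1 for
#' identical partitions up to relabeling, 0 when the mutual information is
#' zero; two all-in-one-cluster partitions are defined as agreeing (NMI 1).
#'
#' @param p,q label vectors over the same node set (any coding).
#' @return NMI in [0, 1].
#' @export
nmi <- function(p, q) {
  if (length(p) != length(q)) stop("labelings differ in length", call. = FALSE)
  tab <- table(p, q)
  N <- sum(tab)
  # identical up to relabeling: exactly one non-zero per row and per column
  if (nrow(tab) == ncol(tab) &&
      all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) return(1)
  pij <- tab / N
  pi_ <- rowSums(pij); pj <- colSums(pij)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pi_, pj)), 0))
  h <- function(x) -sum(ifelse(x > 0, x * log(x), 0))
  denom <- (h(pi_) + h(pj)) / 2
  if (denom == 0) return(1)  # both partitions are single clusters
  max(0, min(1, mi / denom))
}

#' Greedy weighted-modularity baseline
#'
#' Agglomerative (fast-greedy) maximization of Newman's weighted modularity,
#' via [igraph::cluster_fast_greedy]; the descriptive baseline the SBM engine
#' is compared against. Edgeless graphs return singletons.
#'
#' @param graph weighted igraph.
#' @return named 0-based integer label vector.
#' @export
greedyModularity <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot2(n >= 1L, "graph has no nodes")
  if (igraph::ecount(graph) == 0L)
    return(setNames(0:(n - 1L), igraph::V(graph)$name))
  cl <- igraph::cluster_fast_greedy(graph, weights = igraph::E(graph)$weight)
  lab <- as.integer(igraph::membership(cl)) - 1L
  # no split has positive modularity: a single community explains the graph
  q <- igraph::modularity(graph, lab + 1L, weights = igraph::E(graph)$weight)
  if (q <= 1e-12) lab <- rep(0L, n)
  setNames(lab, igraph::V(graph)$name)
}

#' Default benchmark grid
#'
#' Nine heterogeneous weighted network types: topological mixing muTopo in
#' {0.15, 0.30, 0.45} (rows, each row with its own community-size profile,
#' from balanced through skewed) crossed with weight mixing muW in
#' {0.1, 0.5, 0.9} (columns). The weight axis spans the full heterogeneity
#' range: assortative weights (within-community edges heavier), uninformative
#' weights, and inverted weights (between-community edges heavier — weights
#' anti-correlated with the topological communities, a structure descriptive
#' modularity cannot represent but a generative weighted blockmodel can).
#'
#' @param n nodes per network.
#' @return list of nine [lfrSpec()] objects.
#' @export
defaultBenchmarkSpecs <- function(n = 60) {
  rows <- list(list(muTopo = 0.15, minComm = 8, maxComm = 20, tau2 = 1.5),
               list(muTopo = 0.30, minComm = 6, maxComm = 28, tau2 = 2.2),
               list(muTopo = 0.45, minComm = 10, maxComm = 18, tau2 = 1.5))
  specs <- list()
  for (r in rows)
    for (muW in c(0.1, 0.5, 0.9))
      specs <- c(specs, list(lfrSpec(n = n, muTopo = r$muTopo, muW = muW,
                                     minComm = r$minComm, maxComm = r$maxComm,
                                     tau2 = r$tau2)))
  specs
}

#' Run the community-detection benchmark
#'
#' For each network spec and each method, generates `nReps` seeded benchmark
#' instances, runs the method, and scores it against the planted labels with
#' [nmi()]; reports per-(spec, method) mean and sd. A method failure on an
#' instance is recorded as `NA`, not dropped silently.
#'
#' @param specs list of [lfrSpec()] objects.
#' @param methods methods to compare: a character vector among `"sbm"` and
#'   `"greedy"`, and/or a named list of functions `function(graph)` returning
#'   label vectors (e.g. an adapter reading an external partition file via
#'   [readPartition()]).
#' @param nReps instances per spec.
#' @param seed master seed; instance r of spec s uses a derived seed.
#' @param mcmcControl named list of [mcmcPartition()] arguments for the SBM
#'   method.
#' @return list: `table` (data.frame spec x method with meanNMI, sdNMI, nOk)
#'   and `scores` (full per-instance NMI array).
#' @export
runBenchmark <- function(specs, methods = c("sbm", "greedy"), nReps = 10,
                         seed = 1L, mcmcControl = list()) {
  stopifnot2(nReps >= 1, "nReps must be >= 1")
  if (is.character(methods)) methods <- setNames(as.list(methods), methods)
  fns <- lapply(seq_along(methods), function(k) {
    m <- methods[[k]]
    if (is.function(m)) return(m)
    switch(m,
      sbm = function(graph, seed) membershipLabels(
        do.call(mcmcPartition, c(list(graph = graph, seed = seed), mcmcControl))),
      greedy = function(graph, seed) greedyModularity(graph),
      stop("unknown method: ", m, call. = FALSE))
  })
  mnames <- names(methods)
  scores <- array(NA_real_, c(length(specs), length(methods), nReps),
                  dimnames = list(NULL, mnames, NULL))
  for (s in seq_along(specs)) {
    for (r in seq_len(nReps)) {
      instSeed <- deriveSeed(seed, sprintf("lfr-%d-%d", s, r))
      sp <- specs[[s]]
      sp$seed <- instSeed
      net <- lfrGenerate(sp)
      for (k in seq_along(fns)) {
        lab <- tryCatch({
          f <- fns[[k]]
          if (length(formals(f)) >= 2) f(net$graph, deriveSeed(instSeed, mnames[k]))
          else f(net$graph)
        }, error = function(e) NULL)
        if (!is.null(lab)) {
          if (!is.null(names(lab))) lab <- lab[names(net$planted)]
          scores[s, k, r] <- nmi(lab, net$planted)
        }
      }
    }
  }
  rows <- expand.grid(spec = seq_along(specs), method = mnames,
                      stringsAsFactors = FALSE)
  rows$muTopo <- vapply(specs[rows$spec], function(x) x$muTopo, 0)
  rows$muW <- vapply(specs[rows$spec], function(x) x$muW, 0)
  rows$meanNMI <- mapply(function(s, m) mean(scores[s, m, ], na.rm = TRUE),
                         rows$spec, rows$method)
  rows$sdNMI <- mapply(function(s, m) sd(scores[s, m, ], na.rm = TRUE),
                       rows$spec, rows$method)
  rows$nOk <- mapply(function(s, m) sum(!is.na(scores[s, m, ])),
                     rows$spec, rows$method)
  list(table = rows, scores = scores)
}
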