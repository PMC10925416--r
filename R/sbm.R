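#' Build a weighted graph from a symmetric affinity matrix
#'
#' Entries at or above `wMin` (and strictly positive) become undirected
#' weighted edges; isolated nodes are retained. `NA` entries (missing
#' measurements) yield no edge.
#'
#' @param A symmetric non-negative matrix with zero diagonal; weights must
#'   lie in (0, 1].
#' @param wMin edge-inclusion threshold; the default 0 keeps every positive
#'   affinity (sparsification is an explicit user choice).
#' @param ids node names; defaults to rownames(A) or `V1..Vn`.
#' @return an [igraph::igraph] with a `weight` edge attribute and `name`
#'   vertex attribute.
#' @export
graphFromMatrix <- function(A, wMin = 0, ids = NULL) {
  stopifnot2(is.matrix(A) && nrow(A) == ncol(A), "A must be square")
  if (!isTRUE(all.equal(A, t(A), tolerance = 1e-8, check.attributes = FALSE)))
    stop("A must be symmetric", call. = FALSE)
  if (any(diag(A) != 0, na.rm = TRUE)) stop("A must have zero diagonal", call. = FALSE)
  if (any(A < 0, na.rm = TRUE)) stop("A must be non-negative", call. = FALSE)
  if (any(A > 1 + 1e-9, na.rm = TRUE))
    stop("edge weights must lie in (0, 1]; rescale the matrix first", call. = FALSE)
  ids <- ids %||% rownames(A) %||% paste0("V", seq_len(nrow(A)))
  A2 <- A
  A2[is.na(A2)] <- 0
  A2[A2 < wMin] <- 0
  g <- igraph::graph_from_adjacency_matrix(A2, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$name <- ids
  g
}

graphWeightMatrix <- function(graph) {
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  diag(W) <- 0
  W
}

labelsToInt <- function(labels, graph = NULL) {
  if (!is.null(graph) && !is.null(names(labels)))
    labels <- labels[igraph::V(graph)$name]
  if (anyNA(labels)) stop("labels missing for some nodes", call. = FALSE)
  as.integer(as.integer(factor(labels)) - 1L)
}

#' Description length of a partition under the weighted SBM
#'
#' Computes \eqn{\mathcal{L} = -\ln P(G \mid \theta, c) - \ln P(\theta, c)}
#' in nats for the package's weighted stochastic block model: per block pair,
#' Bernoulli edge placement and Beta(theta, 1) edge weights on (0, 1]
#' (equivalently, exponential on -ln w), each with its conjugate prior
#' integrated out in closed form, plus three nested uniform priors on the
#' partition (number of groups, size composition, labeling given sizes).
#' Deterministic given the graph and labeling, and invariant under label
#' permutation. Smaller is better.
#'
#' @param graph weighted igraph (edge attribute `weight` in (0, 1]).
#' @param labels community labels: integer vector over vertices (any coding),
#'   optionally named by vertex.
#' @return description length in nats.
#' @export
descriptionLength <- function(graph, labels) {
  n <- igraph::vcount(graph)
  stopifnot2(length(labels) == n, "labels must cover all nodes")
  if (n == 0L) stop("empty graph", call. = FALSE)
  sbm_dl_cpp(graphWeightMatrix(graph), labelsToInt(labels, graph))
}

#' Infer communities by description-length-minimizing MCMC
#'
#' Metropolis-Hastings over labelings with single-node moves (proposed
#' preferentially toward blocks of a node's neighbors) and merge-split
#' "multi-flip" moves; the number of communities is inferred, not fixed.
#' The chain burns in and samples at unit inverse temperature (collecting
#' per-node label frequencies for model averaging), then anneals to
#' `betaFinal` and finishes with a deterministic greedy polish. The best
#' (minimum description length) state visited is returned; ties are broken
#' toward the lexicographically smallest canonical labeling. Deterministic
#' given `seed`.
#'
#' @param graph weighted igraph.
#' @param seed RNG seed.
#' @param burnin,sampling,anneal sweep counts for the three phases (a sweep
#'   is one move attempt per node plus merge-split attempts).
#' @param betaFinal final inverse temperature of the geometric anneal.
#' @param pNeighbor probability that a single-node proposal targets a random
#'   neighbor's block (the remainder is uniform over blocks plus a new one).
#' @param init optional initial labeling; defaults to singletons followed by
#'   a greedy agglomeration (first restart) and random labelings (later
#'   restarts).
#' @param nRestarts independent search restarts from diverse initial
#'   partitions; the minimum-description-length state over all restarts is
#'   returned (marginals come from the winning chain).
#' @param checkIncremental instrument the run: after every accepted move,
#'   recompute the description length from scratch and record the largest
#'   discrepancy with the incremental bookkeeping (slow; for verification).
#' @return a [CommunityPartition].
#' @export
mcmcPartition <- function(graph, seed = 1L, burnin = 200L, sampling = 800L,
                          anneal = 200L, betaFinal = 5, pNeighbor = 0.9,
                          init = NULL, nRestarts = 3L, checkIncremental = FALSE) {
  n <- igraph::vcount(graph)
  stopifnot2(n >= 1L, "graph has no nodes")
  W <- graphWeightMatrix(graph)
  if (!is.null(init)) nRestarts <- 1L
  res <- NULL
  for (r in seq_len(max(1L, nRestarts))) {
    set.seed(deriveSeed(seed, paste0("sbm-restart-", r)))
    if (!is.null(init)) {
      init_r <- labelsToInt(init, graph)
    } else if (r == 1L) {
      init_r <- 0:(n - 1L)   # singletons -> greedy agglomeration
    } else {
      K <- sample(2:max(2L, ceiling(sqrt(n))), 1L)
      init_r <- sample.int(K, n, replace = TRUE) - 1L
    }
    cand <- sbm_mcmc_cpp(W, as.integer(init_r), as.integer(burnin),
                         as.integer(sampling), as.integer(anneal),
                         betaFinal, pNeighbor, TRUE, checkIncremental)
    if (is.null(res) || cand$dl < res$dl - 1e-12) res <- cand
  }
  labels <- setNames(as.integer(res$labels), igraph::V(graph)$name)
  marg <- res$marginals
  keep <- which(colSums(marg) > 0)
  if (length(keep) == 0L) keep <- 1L
  marg <- marg[, seq_len(max(keep)), drop = FALSE]
  rownames(marg) <- igraph::V(graph)$name
  new("CommunityPartition", labels = labels, dl = res$dl, marginals = marg,
      dlTrace = as.numeric(res$dl_trace), acceptRate = res$accept_rate,
      incrMaxErr = res$incr_max_err)
}

#' Summarize communities, with optional reversion to the original traces
#'
#' Reports each community's members and mean intra/inter edge weights. When
#' a tensor component and the traces are supplied, also reports the
#' component's active time window (temporal factor above half its maximum),
#' the top-loading animals, and per-community trace snippets over that
#' window — the "revert to the original traces" check that a community's
#' members indeed co-vary when and where the component says they do.
#'
#' @param graph weighted igraph over neuron nodes.
#' @param partition a [CommunityPartition] or named label vector.
#' @param model optional [CPModel].
#' @param component component index into `model`.
#' @param traces optional [TraceSet] (for snippets).
#' @param nTopAnimals how many top-loading animals to include.
#' @return list with `communities` (data.frame: community, size, members,
#'   intraWeight, interWeight) and, when a component is given, `window`
#'   (sample range), `topAnimals`, and `snippets` (per community, a list per
#'   top animal of member x time activity matrices).
#' @export
communityReport <- function(graph, partition, model = NULL, component = 1L,
                            traces = NULL, nTopAnimals = 3L) {
  labels <- if (is(partition, "CommunityPartition")) partition@labels else partition
  ids <- igraph::V(graph)$name
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), ids))
      stop("partition names do not match graph nodes: ",
           paste(head(setdiff(ids, names(labels)), 3), collapse = ", "),
           call. = FALSE)
    labels <- labels[ids]
  }
  W <- graphWeightMatrix(graph)
  comms <- sort(unique(labels))
  rows <- lapply(comms, function(cc) {
    inside <- labels == cc
    Win <- W[inside, inside, drop = FALSE]
    Wx <- W[inside, !inside, drop = FALSE]
    intraVals <- Win[upper.tri(Win)]
    data.frame(community = cc, size = sum(inside),
               members = paste(ids[inside], collapse = ","),
               intraWeight = if (length(intraVals)) mean(intraVals[intraVals > 0] %0% 0) else NA_real_,
               interWeight = if (length(Wx)) mean(Wx[Wx > 0] %0% 0) else NA_real_)
  })
  out <- list(communities = do.call(rbind, rows))
  if (!is.null(model)) {
    ft <- model@temporal[, component]
    fw <- model@animal[, component]
    active <- which(ft > max(ft) / 2)
    out$window <- c(min(active), max(active) + 1L)
    out$topAnimals <- order(-fw)[seq_len(min(nTopAnimals, length(fw)))]
    if (!is.null(traces)) {
      missing <- setdiff(ids, traces@neuronIds)
      if (length(missing))
        stop("unknown neuron id(s) in graph: ", paste(head(missing, 3), collapse = ", "),
             call. = FALSE)
      tidx <- out$window[1]:(out$window[2] - 1L)
      out$snippets <- lapply(comms, function(cc) {
        members <- ids[labels == cc]
        midx <- match(members, traces@neuronIds)
        lapply(out$topAnimals, function(w) {
          m <- traces@activity[w, midx, tidx, drop = FALSE]
          dim(m) <- c(length(midx), length(tidx))
          rownames(m) <- members
          m
        })
      })
      names(out$snippets) <- paste0("community", comms)
    }
  }
  out
}

# mean of x, or `alt` when x is empty (keeps report columns well-defined on
# edgeless communities)
`%0%` <- function(x, alt) if (length(x)) x else alt

#' Write a weighted graph as an edge-list TSV or GraphML
#'
#' @param graph weighted igraph.
#' @param path output path; format chosen by extension (`.tsv` edge list
#'   with columns i_id, j_id, weight; `.graphml` via igraph).
#' @export
writeGraph <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(i_id = el[, 1], j_id = el[, 2],
                     weight = igraph::E(graph)$weight)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
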