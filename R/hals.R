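# Non-negative CP decomposition by hierarchical alternating least squares.
#
# Each factor column is updated in closed form against the mode-k unfolding
# (matricized tensor times Khatri-Rao product), clipped at zero. Missing
# entries are handled EM-style: they are imputed with the current
# reconstruction at the top of every outer iteration, so they never enter
# the reported (observed-entry) objective, which is non-increasing.

# mode-k unfolding of a T x W x P array; columns ordered with the earlier
# remaining mode varying fastest (Kolda-Bader convention)
unfoldMode <- function(X, k) {
  d <- dim(X)
  switch(k,
         matrix(X, d[1], d[2] * d[3]),
         matrix(aperm(X, c(2, 1, 3)), d[2], d[1] * d[3]),
         matrix(aperm(X, c(3, 1, 2)), d[3], d[1] * d[2]))
}

halsSingle <- function(X, mask, R, seed, maxIter, tol) {
  d <- dim(X)
  allObserved <- all(mask)
  Xobs <- X
  Xobs[!mask] <- 0
  mObs <- sum(mask)
  set.seed(seed)
  mu <- if (mObs > 0) sum(Xobs) / mObs else 0
  if (mu <= 0) {  # all-zero (or empty) observed data: exact zero model
    U <- lapply(d, function(I) matrix(0, I, R))
    return(list(U = U, objHistory = 0, iterations = 0L, converged = TRUE))
  }
  scl <- 2 * (mu / R)^(1 / 3)
  U <- lapply(d, function(I) matrix(runif(I * R) * scl, I, R))
  Xw <- X
  Xw[!mask] <- mu
  objHistory <- numeric(0)
  objPrev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    for (k in 1:3) {
      others <- setdiff(1:3, k)
      a <- others[1]; b <- others[2]
      K <- khatriRao(U[[b]], U[[a]])                  # rows: mode-a fastest
      G <- crossprod(U[[a]]) * crossprod(U[[b]])
      M <- unfoldMode(Xw, k) %*% K
      Uk <- U[[k]]
      for (r in seq_len(R)) {
        g <- G[r, r]
        if (g < 1e-12) { Uk[, r] <- 0; next }
        Uk[, r] <- pmax(0, Uk[, r] + (M[, r] - Uk %*% G[, r]) / g)
      }
      U[[k]] <- Uk
    }
    recFlat <- U[[1]] %*% t(khatriRao(U[[3]], U[[2]]))
    rec <- array(recFlat, d)
    obj <- 0.5 * sum((Xobs - rec)[mask]^2)
    objHistory <- c(objHistory, obj)
    if (!allObserved) { Xw <- X; Xw[!mask] <- rec[!mask] }
    if (is.finite(objPrev) && abs(objPrev - obj) <= tol * max(objPrev, 1e-300)) {
      converged <- TRUE
      break
    }
    objPrev <- obj
  }
  list(U = U, objHistory = objHistory, iterations = it, converged = converged)
}

# normalize columns to unit norm, fold scales into lambda, sort descending
canonicalizeCP <- function(U, pairs, neuronIds, animalIds, fit, seed) {
  R <- ncol(U[[1]])
  nrms <- vapply(U, function(M) sqrt(colSums(M^2)), numeric(R))
  if (R == 1L) nrms <- matrix(nrms, 1, 3)
  lambda <- apply(nrms, 1, prod)
  for (k in 1:3) {
    nz <- nrms[, k] > 0
    U[[k]][, nz] <- sweep(U[[k]][, nz, drop = FALSE], 2, nrms[nz, k], `/`)
    U[[k]][, !nz] <- 0
  }
  ord <- order(-lambda)
  new("CPModel", rank = as.integer(R), lambda = lambda[ord],
      temporal = U[[1]][, ord, drop = FALSE],
      animal = U[[2]][, ord, drop = FALSE],
      affinity = U[[3]][, ord, drop = FALSE],
      objective = if (length(fit$objHistory)) fit$objHistory[length(fit$objHistory)] else 0,
      objHistory = if (length(fit$objHistory)) fit$objHistory else 0,
      seed = as.integer(seed),
      iterations = fit$iterations, converged = fit$converged,
      pairs = pairs, neuronIds = neuronIds, animalIds = animalIds)
}

#' Fit a non-negative CP decomposition by HALS
#'
#' Minimizes the masked squared reconstruction error
#' \eqn{\frac12 \lVert T - \tilde T \rVert^2} (summed over observed entries
#' only) over non-negative factor matrices, by cyclic closed-form column
#' updates (HALS). Missing entries are imputed with the current
#' reconstruction at each outer iteration (EM-style), so perturbing them
#' never changes the fit. Several random restarts are run and the best
#' objective kept; everything is deterministic given `seed`.
#'
#' @param tensor an [AffinityTensor], or a plain numeric 3-way array (taken
#'   as fully observed).
#' @param rank number of components R (>= 1). A rank exceeding a tensor
#'   dimension is allowed with a warning.
#' @param nRestarts random restarts (default 10); restart k uses seed
#'   `seed + k - 1`.
#' @param seed base RNG seed.
#' @param maxIter,tol outer-iteration cap and relative objective-change
#'   stopping tolerance.
#' @return a [CPModel] (components unit-norm with explicit `lambda`, sorted
#'   by decreasing `lambda`; `objHistory` is non-increasing).
#' @export
halsFit <- function(tensor, rank, nRestarts = 10, seed = 1L, maxIter = 500L,
                    tol = 1e-7) {
  if (is(tensor, "AffinityTensor")) {
    X <- tensor@data; mask <- tensor@mask
    pairs <- tensor@pairs; nids <- tensor@neuronIds; aids <- tensor@animalIds
  } else {
    X <- tensor; mask <- array(TRUE, dim(X))
    pairs <- matrix(integer(0), 0, 2); nids <- character(0); aids <- character(0)
  }
  stopifnot2(length(dim(X)) == 3L, "tensor must be 3-way")
  stopifnot2(rank >= 1L, "rank must be >= 1")
  stopifnot2(sum(mask) > 0, "tensor has no observed entries")
  if (rank > min(dim(X)))
    warning("rank exceeds a tensor dimension; components may be degenerate")
  best <- NULL
  bestObj <- Inf
  bestSeed <- NA_integer_
  for (k in seq_len(nRestarts)) {
    sk <- as.integer(seed) + k - 1L
    fit <- halsSingle(X, mask, rank, sk, maxIter, tol)
    obj <- if (length(fit$objHistory)) fit$objHistory[length(fit$objHistory)] else 0
    if (is.null(best) || obj < bestObj - 1e-15) {
      best <- fit; bestObj <- obj; bestSeed <- sk
    }
  }
  canonicalizeCP(best$U, pairs, nids, aids, best, bestSeed)
}

#' Align two CP models and score their factor congruence
#'
#' Components are matched by the permutation maximizing total similarity,
#' where the similarity of two components is the mean over the three modes
#' of the absolute cosine between their (unit-norm) factors; scale and sign
#' indeterminacies therefore do not count against the score. For ranks up to
#' 8 the optimal permutation is found by enumeration, above that greedily.
#'
#' @param a,b [CPModel]s (or lists with `temporal`, `animal`, `affinity`) of
#'   equal rank.
#' @return list with `score` (minimum matched similarity over components),
#'   `meanScore`, `perComponent`, and the permutation `perm` (b's component
#'   matched to each of a's).
#' @export
factorCongruence <- function(a, b) {
  fa <- if (is(a, "CPModel")) factorMatrices(a) else a
  fb <- if (is(b, "CPModel")) factorMatrices(b) else b
  R <- ncol(fa$temporal)
  stopifnot2(ncol(fb$temporal) == R, "models must have equal rank")
  cosAbs <- function(A, B) {
    An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-300), `/`)
    Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), 1e-300), `/`)
    abs(crossprod(An, Bn))
  }
  S <- (cosAbs(fa$temporal, fb$temporal) + cosAbs(fa$animal, fb$animal) +
        cosAbs(fa$affinity, fb$affinity)) / 3
  if (R <= 8) {
    perms <- permEnum(R)
    tot <- vapply(perms, function(p) sum(S[cbind(seq_len(R), p)]), 0)
    perm <- perms[[which.max(tot)]]
  } else {
    perm <- integer(R)
    avail <- seq_len(R)
    for (r in seq_len(R)) {
      perm[r] <- avail[which.max(S[r, avail])]
      avail <- setdiff(avail, perm[r])
    }
  }
  per <- S[cbind(seq_len(R), perm)]
  list(score = min(per), meanScore = mean(per), perComponent = per, perm = perm)
}

permEnum <- function(R) {
  if (R == 1L) return(list(1L))
  sub <- permEnum(R - 1L)
  out <- list()
  for (p in sub)
    for (pos in seq_len(R))
      out[[length(out) + 1L]] <- append(p, R, after = pos - 1L)
  out
}

#' Rank-selection diagnostics
#'
#' For each candidate rank, runs independent seeded restarts and reports the
#' best objective and a stability score: the mean pairwise factor congruence
#' (mean matched similarity) across restarts. Overfit ranks split components
#' inconsistently across restarts and score low; no automatic choice is
#' imposed.
#'
#' @param tensor an [AffinityTensor] or 3-way array.
#' @param ranks integer vector of candidate ranks.
#' @param nRestarts restarts per rank.
#' @param seed base seed; restart k of any rank uses `seed + k - 1`.
#' @param maxIter,tol passed to the fits.
#' @return data.frame with one row per rank: `rank`, `bestObjective`,
#'   `stability`, `nRestarts`.
#' @export
selectRank <- function(tensor, ranks, nRestarts = 5, seed = 1L,
                       maxIter = 200L, tol = 1e-6) {
  stopifnot2(length(ranks) >= 1, "ranks must be non-empty")
  rows <- lapply(ranks, function(R) {
    fits <- lapply(seq_len(nRestarts), function(k)
      halsFit(tensor, R, nRestarts = 1, seed = as.integer(seed) + k - 1L,
              maxIter = maxIter, tol = tol))
    objs <- vapply(fits, function(f) f@objective, 0)
    stab <- NA_real_
    if (nRestarts >= 2) {
      prs <- combn(nRestarts, 2)
      stab <- mean(apply(prs, 2, function(ix)
        factorCongruence(fits[[ix[1]]], fits[[ix[2]]])$meanScore))
    }
    data.frame(rank = R, bestObjective = min(objs), stability = stab,
               nRestarts = nRestarts)
  })
  do.call(rbind, rows)
}
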