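#' Upper-triangular pair indexing
#'
#' Bijection between neuron pairs (i < j) and `1..n(n-1)/2`, row-lexicographic
#' by (i, j), 1-based. Only the upper triangle of a symmetric affinity matrix
#' is vectorized.
#'
#' @param n number of neurons (>= 2).
#' @return integer matrix with `n(n-1)/2` rows and columns `i`, `j`.
#' @export
pairIndex <- function(n) {
  stopifnot2(n >= 2, "need n >= 2")
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @rdname pairIndex
#' @param i,j 1-based neuron indices with `i < j`.
#' @export
pairToIndex <- function(i, j, n) {
  stopifnot2(all(i >= 1 & j <= n & i < j), "need 1 <= i < j <= n")
  as.integer((i - 1) * (2 * n - i) / 2 + (j - i))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Row-lexicographic (i < j) order, matching [pairIndex()]. Inverse of
#' [factorToMatrix()].
#'
#' @param A symmetric matrix.
#' @return numeric vector of length `n(n-1)/2`.
#' @export
vectorizeMatrix <- function(A) {
  t(A)[lower.tri(A)]
}

#' Reshape a pair vector into a symmetric matrix
#'
#' Inverse of [vectorizeMatrix()]: places a vectorized affinity pattern (for
#' example one affinity factor of a [CPModel]) back into a symmetric,
#' zero-diagonal n x n matrix.
#'
#' @param v numeric vector of length `n(n-1)/2`.
#' @param ids optional row/column names (neuron ids); its length fixes n.
#' @return symmetric n x n matrix.
#' @export
factorToMatrix <- function(v, ids = NULL) {
  P <- length(v)
  n <- (1 + sqrt(1 + 8 * P)) / 2
  if (n != round(n)) stop("length is not n(n-1)/2 for integer n", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(ids) && length(ids) != n)
    stop(sprintf("ids has length %d but the vector implies n = %d", length(ids), n),
         call. = FALSE)
  pm <- pairIndex(n)
  A <- matrix(0, n, n)
  A[cbind(pm[, 1], pm[, 2])] <- v
  A[cbind(pm[, 2], pm[, 1])] <- v
  if (!is.null(ids)) dimnames(A) <- list(ids, ids)
  A
}

#' Build the TIME x ANIMALS x PAIR-AFFINITIES tensor
#'
#' `data[t, w, p] = a_wp(t)`; the mask is `FALSE` wherever either neuron of
#' pair p is unobserved in animal w (those entries carry no measurement and
#' are excluded from factorization objectives — the factorization can then
#' impute, i.e. "complete", them).
#'
#' @param aff an [AffinitySeries].
#' @return an [AffinityTensor].
#' @export
buildTensor <- function(aff) {
  stopifnot2(is(aff, "AffinitySeries"), "aff must be an AffinitySeries")
  dataTWP <- aperm(aff@values, c(3, 1, 2))
  T <- dim(dataTWP)[1]; W <- dim(dataTWP)[2]; P <- dim(dataTWP)[3]
  # observedPairs is W x P; replicate over time
  mask <- array(FALSE, c(T, W, P))
  for (w in seq_len(W)) mask[, w, ] <- matrix(aff@observedPairs[w, ], T, P, byrow = TRUE)
  new("AffinityTensor", data = dataTWP, mask = mask, pairs = aff@pairs,
      neuronIds = aff@neuronIds, animalIds = aff@animalIds, dt = aff@dt)
}

# column-wise Khatri-Rao product: column r is kronecker(A[,r], B[,r])
khatriRao <- function(A, B) {
  R <- ncol(A)
  out <- matrix(0, nrow(A) * nrow(B), R)
  for (r in seq_len(R)) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' Reconstruct the dense tensor from a CP model
#'
#' \deqn{\tilde T = \sum_r \lambda_r\, v_r^{(1)} \circ v_r^{(2)} \circ v_r^{(3)}}
#' with the temporal, animal and affinity factors as modes 1-3.
#'
#' @param model a [CPModel], or a list with elements `lambda`, `temporal`,
#'   `animal`, `affinity`.
#' @return numeric array T x W x P, entrywise non-negative.
#' @export
cpReconstruct <- function(model) {
  f <- if (is(model, "CPModel")) factorMatrices(model) else model
  lambda <- if (is(model, "CPModel")) model@lambda else model$lambda
  U1 <- f$temporal; U2 <- f$animal; U3 <- f$affinity
  U1l <- sweep(U1, 2, lambda, `*`)
  flat <- U1l %*% t(khatriRao(U3, U2))      # T x (W*P), w varying fastest
  array(flat, c(nrow(U1), nrow(U2), nrow(U3)))
}
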