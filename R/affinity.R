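#' Smoothed derivatives of activity traces
#'
#' Each trace is convolved with a Gaussian kernel (reflective boundary
#' handling), then differentiated by central differences (one-sided at the
#' ends), giving derivatives in activity units per second. The operator is
#' linear in the traces. Unobserved neurons get an all-zero derivative row;
#' their absence is carried in the mask.
#'
#' @param traces a [TraceSet].
#' @param sigma Gaussian bandwidth in seconds; 0 skips smoothing. Default:
#'   4 samples (`4 * dt`).
#' @return a [DerivativeField].
#' @export
smoothDerivative <- function(traces, sigma = NULL) {
  stopifnot2(is(traces, "TraceSet"), "traces must be a TraceSet")
  stopifnot2(nTime(traces) >= 3L, "need at least 3 time points")
  sigma <- sigma %||% (4 * traces@dt)
  stopifnot2(sigma >= 0, "sigma must be >= 0")
  A <- nAnimals(traces); N <- nNeurons(traces); T <- nTime(traces)
  flat <- matrix(aperm(traces@activity, c(3, 1, 2)), nrow = T)  # T x (A*N)
  flat <- t(flat)                                               # series x T
  flat[!is.finite(flat)] <- 0
  sm <- gaussianSmoothRows(flat, sigma / traces@dt)
  dd <- centralDiffRows(sm, traces@dt)
  d <- aperm(array(t(dd), c(T, A, N)), c(2, 3, 1))
  for (w in seq_len(A)) d[w, !traces@observed[w, ], ] <- 0
  new("DerivativeField", d = d, sigma = sigma, dt = traces@dt,
      neuronIds = traces@neuronIds, animalIds = traces@animalIds,
      observed = traces@observed)
}

#' Maximal monotone segments of the derivative field
#'
#' Assigns each time point the sign of the smoothed derivative, zeroing
#' magnitudes below `zeroBand`, then discards constant-sign runs shorter
#' than `minDuration`. A sign of 0 means the time point belongs to no
#' monotone segment.
#'
#' @param d a [DerivativeField].
#' @param zeroBand derivative magnitude under which the sign is treated as 0;
#'   scalar or one value per animal. Default: per-animal 75th percentile of
#'   the absolute derivative over observed neurons — a noise-scale band,
#'   under the working assumption that circuit activity is transient so most
#'   samples carry only noise-level change. Derivatives inside the band give
#'   no evidence of monotone change.
#' @param minDuration minimum segment duration in seconds; default 3 samples.
#' @return a [MonotoneSegments].
#' @export
monotoneSegments <- function(d, zeroBand = NULL, minDuration = NULL) {
  stopifnot2(is(d, "DerivativeField"), "d must be a DerivativeField")
  A <- dim(d@d)[1]; N <- dim(d@d)[2]; T <- dim(d@d)[3]
  minDuration <- minDuration %||% (3 * d@dt)
  if (is.null(zeroBand)) {
    zeroBand <- vapply(seq_len(A), function(w) {
      obs <- d@observed[w, ]
      if (!any(obs)) return(0)
      as.numeric(quantile(abs(d@d[w, obs, ]), 0.75))
    }, 0)
  }
  stopifnot2(all(zeroBand >= 0), "zeroBand must be >= 0")
  if (length(zeroBand) == 1L) zeroBand <- rep(zeroBand, A)
  stopifnot2(length(zeroBand) == A, "zeroBand must be scalar or one per animal")
  minLen <- max(1L, as.integer(round(minDuration / d@dt)))
  signs <- array(0L, dim(d@d))
  for (w in seq_len(A)) {
    dw <- d@d[w, , , drop = FALSE]
    dim(dw) <- c(N, T)
    sw <- matrix(0L, N, T)
    sw[dw > zeroBand[w]] <- 1L
    sw[dw < -zeroBand[w]] <- -1L
    for (i in seq_len(N)) {
      if (!d@observed[w, i]) { sw[i, ] <- 0L; next }
      r <- rle(sw[i, ])
      r$values[r$values != 0L & r$lengths < minLen] <- 0L
      sw[i, ] <- inverse.rle(r)
    }
    signs[w, , ] <- sw
  }
  new("MonotoneSegments", signs = signs, zeroBand = zeroBand,
      minDuration = minDuration, dt = d@dt)
}

#' Segment table for one trace
#'
#' Convenience view of [monotoneSegments()] output: the maximal constant-sign
#' runs of one (animal, neuron) series as a data frame of half-open sample
#' intervals.
#'
#' @param segs a [MonotoneSegments].
#' @param animal,neuron indices.
#' @return data.frame with columns `start`, `end` (half-open, 1-based) and
#'   `sign`.
#' @export
segmentTable <- function(segs, animal, neuron) {
  s <- segs@signs[animal, neuron, ]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.frame(start = starts[keep], end = ends[keep] + 1L, sign = r$values[keep])
}

#' Local differential affinity between neuron pairs
#'
#' For each animal, pair (i, j) and time t, the affinity is 0 unless t lies
#' inside a monotone segment of both neurons; otherwise
#' \deqn{a_{ij}(t) = \frac{\min(|d_i|, |d_j|)}{\max(|d_i|, |d_j|)}
#'   \left(1 - e^{-\max(|d_i|, |d_j|)/\kappa}\right),}
#' the agreement ratio of the absolute derivatives times a magnitude gate
#' that suppresses coincidences of near-zero derivatives. Values lie in
#' [0, 1]. Because only absolute derivatives enter, anti-correlated pairs
#' score as high as correlated ones. The functional form is isolated here so
#' an alternative kernel can be swapped without touching the rest of the
#' pipeline.
#'
#' @param d a [DerivativeField].
#' @param segs a [MonotoneSegments] computed from `d`.
#' @param kappa magnitude-gate scale (same units as the derivatives);
#'   `kappa = 0` disables the gate (gate = 1 wherever the larger derivative
#'   is positive). Default: 90th percentile of the absolute derivative over
#'   observed data, so that only clearly supra-noise derivative coincidences
#'   pass the gate at full strength.
#' @return an [AffinitySeries].
#' @export
differentialAffinity <- function(d, segs, kappa = NULL) {
  stopifnot2(is(d, "DerivativeField"), "d must be a DerivativeField")
  stopifnot2(is(segs, "MonotoneSegments"), "segs must be MonotoneSegments")
  A <- dim(d@d)[1]; N <- dim(d@d)[2]; T <- dim(d@d)[3]
  if (is.null(kappa)) {
    vals <- unlist(lapply(seq_len(A), function(w) abs(d@d[w, d@observed[w, ], ])))
    kappa <- if (length(vals)) as.numeric(quantile(vals, 0.9)) else 0
  }
  stopifnot2(kappa >= 0, "kappa must be >= 0")
  pairs <- pairIndex(N)
  P <- nrow(pairs)
  values <- array(0, c(A, P, T))
  observedPairs <- matrix(FALSE, A, P)
  for (w in seq_len(A)) {
    D <- abs(matrix(d@d[w, , ], N, T))
    Z <- matrix(segs@signs[w, , ], N, T) != 0L
    for (p in seq_len(P)) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      both <- Z[i, ] & Z[j, ]
      if (!any(both)) next
      hi <- pmax(D[i, ], D[j, ])
      lo <- pmin(D[i, ], D[j, ])
      gate <- if (kappa > 0) 1 - exp(-hi / kappa) else as.numeric(hi > 0)
      a <- ifelse(both & hi > 0, lo / hi * gate, 0)
      values[w, p, ] <- a
    }
    observedPairs[w, ] <- d@observed[w, pairs[, 1]] & d@observed[w, pairs[, 2]]
  }
  new("AffinitySeries", values = values, pairs = pairs,
      observedPairs = observedPairs, neuronIds = d@neuronIds,
      animalIds = d@animalIds, dt = d@dt,
      params = list(sigma = d@sigma, zeroBand = segs@zeroBand,
                    minDuration = segs@minDuration, kappa = kappa))
}

#' One-call affinity computation with package defaults
#'
#' Runs [smoothDerivative()], [monotoneSegments()] and
#' [differentialAffinity()] with the documented defaults; every parameter is
#' overridable and the resolved values are recorded in the result's `params`.
#'
#' @inheritParams smoothDerivative
#' @inheritParams monotoneSegments
#' @inheritParams differentialAffinity
#' @return an [AffinitySeries].
#' @export
affinitySeries <- function(traces, sigma = NULL, zeroBand = NULL,
                           minDuration = NULL, kappa = NULL) {
  d <- smoothDerivative(traces, sigma)
  segs <- monotoneSegments(d, zeroBand, minDuration)
  differentialAffinity(d, segs, kappa)
}

#' Bundle one time slice into a symmetric affinity matrix
#'
#' @param aff an [AffinitySeries].
#' @param t time index (1-based sample).
#' @param animal animal index.
#' @return symmetric n x n matrix `A(t)` with zero diagonal; rows/columns of
#'   unobserved neurons are `NA` (missing, not zero).
#' @export
bundleMatrix <- function(aff, t, animal) {
  stopifnot2(is(aff, "AffinitySeries"), "aff must be an AffinitySeries")
  T <- dim(aff@values)[3]
  stopifnot2(t >= 1 && t <= T, "t out of range")
  n <- length(aff@neuronIds)
  A <- matrix(0, n, n, dimnames = list(aff@neuronIds, aff@neuronIds))
  v <- aff@values[animal, , t]
  v[!aff@observedPairs[animal, ]] <- NA_real_
  A[cbind(aff@pairs[, 1], aff@pairs[, 2])] <- v
  A[cbind(aff@pairs[, 2], aff@pairs[, 1])] <- v
  A
}
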