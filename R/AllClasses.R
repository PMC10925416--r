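#' TraceSet: multi-animal neural activity traces
#'
#' Container for per-animal neuron-by-time activity matrices sharing one
#' neuron namespace and one time axis. Neurons missing from an animal's
#' recording are flagged in the `observed` mask rather than zero-filled.
#'
#' @slot activity numeric array, animals x neurons x time.
#' @slot neuronIds character vector of neuron names (columns of the shared
#'   namespace).
#' @slot animalIds character vector of animal identifiers.
#' @slot observed logical matrix, animals x neurons; `FALSE` marks neurons not
#'   recorded in that animal.
#' @slot dt sampling interval in seconds.
#' @export
setClass("TraceSet",
  representation(activity = "array", neuronIds = "character",
                 animalIds = "character", observed = "matrix", dt = "numeric"),
  validity = function(object) {
    d <- dim(object@activity)
    if (length(d) != 3L) return("activity must be a 3-way array (animal x neuron x time)")
    if (d[2] < 2L) return("need at least 2 neurons")
    if (d[1] < 1L) return("need at least 1 animal")
    if (length(object@neuronIds) != d[2]) return("neuronIds length must match dim 2")
    if (length(object@animalIds) != d[1]) return("animalIds length must match dim 1")
    if (anyDuplicated(object@neuronIds)) return("duplicate neuron ids")
    if (!identical(dim(object@observed), d[1:2])) return("observed must be animals x neurons")
    if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
      return("dt must be a single positive number")
    for (w in seq_len(d[1])) {
      obs <- object@observed[w, ]
      if (any(obs) && !all(is.finite(object@activity[w, obs, , drop = FALSE])))
        return(sprintf("non-finite activity for an observed neuron in animal '%s'",
                       object@animalIds[w]))
    }
    TRUE
  })

#' DerivativeField: smoothed trace derivatives
#'
#' @slot d numeric array animals x neurons x time of smoothed derivatives
#'   (units of activity per second).
#' @slot sigma Gaussian smoothing bandwidth in seconds.
#' @slot dt sampling interval in seconds.
#' @slot neuronIds,animalIds namespaces inherited from the [TraceSet].
#' @slot observed logical animals x neurons mask.
#' @export
setClass("DerivativeField",
  representation(d = "array", sigma = "numeric", dt = "numeric",
                 neuronIds = "character", animalIds = "character",
                 observed = "matrix"))

#' MonotoneSegments: maximal constant-sign derivative runs
#'
#' Stores, per (animal, neuron, time), the derivative sign in {-1, 0, +1}
#' after zero-banding and minimum-duration filtering; 0 means the time point
#' belongs to no monotone segment.
#'
#' @slot signs integer array animals x neurons x time.
#' @slot zeroBand per-animal derivative magnitude below which the sign is 0.
#' @slot minDuration minimum segment duration in seconds.
#' @slot dt sampling interval in seconds.
#' @export
setClass("MonotoneSegments",
  representation(signs = "array", zeroBand = "numeric",
                 minDuration = "numeric", dt = "numeric"))

#' AffinitySeries: time-resolved pairwise differential affinities
#'
#' @slot values numeric array animals x pairs x time with entries in [0, 1];
#'   zero outside shared monotone segments.
#' @slot pairs integer matrix (pairs x 2) of 1-based neuron index pairs (i < j),
#'   row-lexicographic.
#' @slot observedPairs logical animals x pairs; `FALSE` where either neuron of
#'   the pair is unobserved in that animal (values there are placeholders, not
#'   measurements).
#' @slot neuronIds,animalIds namespaces.
#' @slot dt sampling interval in seconds.
#' @slot params list of the affinity parameters used (sigma, zeroBand,
#'   minDuration, kappa).
#' @export
setClass("AffinitySeries",
  representation(values = "array", pairs = "matrix", observedPairs = "matrix",
                 neuronIds = "character", animalIds = "character",
                 dt = "numeric", params = "list"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be animals x pairs x time")
    if (nrow(object@pairs) != dim(v)[2]) return("pairs rows must match dim 2")
    n <- length(object@neuronIds)
    if (nrow(object@pairs) != n * (n - 1) / 2) return("pairs must enumerate all n(n-1)/2 pairs")
    rng <- range(v)
    if (rng[1] < -1e-12 || rng[2] > 1 + 1e-12) return("affinities must lie in [0, 1]")
    TRUE
  })

#' AffinityTensor: TIME x ANIMALS x PAIR-AFFINITIES array with mask
#'
#' @slot data numeric array T x W x P, P = n(n-1)/2, non-negative where
#'   observed.
#' @slot mask logical array of the same shape; `FALSE` entries are missing
#'   (unobserved neuron pairs) and are excluded from factorization objectives.
#' @slot pairs integer matrix (P x 2), 1-based (i < j) row-lexicographic.
#' @slot neuronIds,animalIds namespaces.
#' @slot dt sampling interval in seconds.
#' @export
setClass("AffinityTensor",
  representation(data = "array", mask = "array", pairs = "matrix",
                 neuronIds = "character", animalIds = "character", dt = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 3L) return("data must be a 3-way array")
    if (!identical(dim(object@mask), d)) return("mask shape must match data")
    n <- length(object@neuronIds)
    if (d[3] != n * (n - 1) / 2) return("dim 3 must equal n(n-1)/2")
    if (any(object@data[object@mask] < -1e-12)) return("observed entries must be non-negative")
    TRUE
  })

#' CPModel: non-negative canonical polyadic decomposition
#'
#' R components, each a triple of non-negative factors: temporal (when),
#' animal (in whom), affinity (between which neuron pairs). All factor
#' columns have unit Euclidean norm with the scale carried by `lambda`;
#' components are sorted by decreasing `lambda`.
#'
#' @slot rank number of components R.
#' @slot lambda per-component scale, length R, non-increasing.
#' @slot temporal T x R non-negative factor matrix.
#' @slot animal W x R non-negative factor matrix.
#' @slot affinity P x R non-negative factor matrix.
#' @slot objective final value of the masked squared-error objective.
#' @slot objHistory objective value after each outer iteration (of the best
#'   restart); non-increasing.
#' @slot seed,iterations,converged fit metadata.
#' @slot pairs,neuronIds,animalIds namespaces carried over from the tensor.
#' @export
setClass("CPModel",
  representation(rank = "integer", lambda = "numeric", temporal = "matrix",
                 animal = "matrix", affinity = "matrix", objective = "numeric",
                 objHistory = "numeric", seed = "integer", iterations = "integer",
                 converged = "logical", pairs = "matrix",
                 neuronIds = "character", animalIds = "character"),
  validity = function(object) {
    R <- object@rank
    if (ncol(object@temporal) != R || ncol(object@animal) != R ||
        ncol(object@affinity) != R) return("factor matrices must have R columns")
    if (length(object@lambda) != R) return("lambda must have length R")
    if (min(object@temporal, object@animal, object@affinity, 0) < -1e-12)
      return("factors must be non-negative")
    if (is.unsorted(rev(object@lambda), strictly = FALSE))
      return("components must be sorted by decreasing lambda")
    TRUE
  })

#' CommunityPartition: node labeling with its description length
#'
#' @slot labels named integer vector, node -> community label in 0..C-1
#'   (contiguous, canonical first-occurrence order).
#' @slot dl description length (nats) of the labeling under the weighted SBM.
#' @slot marginals nodes x labels matrix of posterior label frequencies over
#'   post-burn-in samples (rows sum to 1); zero columns trimmed.
#' @slot dlTrace per-sweep description length of the sampler.
#' @slot acceptRate Metropolis acceptance rate.
#' @slot incrMaxErr largest |incremental - recomputed| description-length
#'   discrepancy observed (only populated in instrumented runs).
#' @export
setClass("CommunityPartition",
  representation(labels = "integer", dl = "numeric", marginals = "matrix",
                 dlTrace = "numeric", acceptRate = "numeric",
                 incrMaxErr = "numeric"),
  validity = function(object) {
    lab <- object@labels
    if (length(lab) == 0L) return("empty labeling")
    C <- max(lab) + 1L
    if (!setequal(unique(lab), 0:(C - 1L))) return("labels must be contiguous 0..C-1")
    if (!is.finite(object@dl)) return("description length must be finite")
    TRUE
  })
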