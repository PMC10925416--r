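#' @name accessors
#' @title Accessors for dynconn objects
#' @description Small accessor generics used across the package's S4 classes.
#' @param x an object.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("activity", function(x, ...) standardGeneric("activity"))
#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x, ...) standardGeneric("neuronIds"))
#' @rdname accessors
#' @export
setGeneric("animalIds", function(x, ...) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(x, ...) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x, ...) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @rdname accessors
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname accessors
#' @export
setGeneric("nTime", function(x) standardGeneric("nTime"))
#' @rdname accessors
#' @export
setGeneric("affinityValues", function(x, ...) standardGeneric("affinityValues"))
#' @rdname accessors
#' @export
setGeneric("pairMap", function(x, ...) standardGeneric("pairMap"))
#' @rdname accessors
#' @export
setGeneric("tensorData", function(x, ...) standardGeneric("tensorData"))
#' @rdname accessors
#' @export
setGeneric("tensorMask", function(x, ...) standardGeneric("tensorMask"))
#' @rdname accessors
#' @export
setGeneric("factorMatrices", function(x, ...) standardGeneric("factorMatrices"))
#' @rdname accessors
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))
#' @rdname accessors
#' @export
setGeneric("objectiveHistory", function(x) standardGeneric("objectiveHistory"))
#' @rdname accessors
#' @export
setGeneric("membershipLabels", function(x, ...) standardGeneric("membershipLabels"))

#' @rdname accessors
#' @export
setMethod("activity", "TraceSet", function(x, ...) x@activity)
#' @rdname accessors
#' @export
setMethod("neuronIds", "TraceSet", function(x, ...) x@neuronIds)
#' @rdname accessors
#' @export
setMethod("animalIds", "TraceSet", function(x, ...) x@animalIds)
#' @rdname accessors
#' @export
setMethod("observedMask", "TraceSet", function(x, ...) x@observed)
#' @rdname accessors
#' @export
setMethod("samplingInterval", "TraceSet", function(x, ...) x@dt)
#' @rdname accessors
#' @export
setMethod("nNeurons", "TraceSet", function(x) dim(x@activity)[2])
#' @rdname accessors
#' @export
setMethod("nAnimals", "TraceSet", function(x) dim(x@activity)[1])
#' @rdname accessors
#' @export
setMethod("nTime", "TraceSet", function(x) dim(x@activity)[3])

#' @rdname accessors
#' @export
setMethod("affinityValues", "AffinitySeries", function(x, ...) x@values)
#' @rdname accessors
#' @export
setMethod("pairMap", "AffinitySeries", function(x, ...) x@pairs)
#' @rdname accessors
#' @export
setMethod("neuronIds", "AffinitySeries", function(x, ...) x@neuronIds)
#' @rdname accessors
#' @export
setMethod("animalIds", "AffinitySeries", function(x, ...) x@animalIds)
#' @rdname accessors
#' @export
setMethod("observedMask", "AffinitySeries", function(x, ...) x@observedPairs)

#' @rdname accessors
#' @export
setMethod("tensorData", "AffinityTensor", function(x, ...) x@data)
#' @rdname accessors
#' @export
setMethod("tensorMask", "AffinityTensor", function(x, ...) x@mask)
#' @rdname accessors
#' @export
setMethod("pairMap", "AffinityTensor", function(x, ...) x@pairs)
#' @rdname accessors
#' @export
setMethod("neuronIds", "AffinityTensor", function(x, ...) x@neuronIds)

#' @rdname accessors
#' @export
setMethod("factorMatrices", "CPModel", function(x, ...)
  list(temporal = x@temporal, animal = x@animal, affinity = x@affinity))
#' @rdname accessors
#' @export
setMethod("lambdas", "CPModel", function(x) x@lambda)
#' @rdname accessors
#' @export
setMethod("objectiveHistory", "CPModel", function(x) x@objHistory)
#' @rdname accessors
#' @export
setMethod("pairMap", "CPModel", function(x, ...) x@pairs)
#' @rdname accessors
#' @export
setMethod("neuronIds", "CPModel", function(x, ...) x@neuronIds)

#' @rdname accessors
#' @export
setMethod("membershipLabels", "CommunityPartition", function(x, ...) x@labels)

setMethod("show", "TraceSet", function(object) {
  d <- dim(object@activity)
  cat(sprintf("TraceSet: %d animals x %d neurons x %d time points (dt = %g s)\n",
              d[1], d[2], d[3], object@dt))
  cat(sprintf("  observed: %d / %d (animal, neuron) entries\n",
              sum(object@observed), length(object@observed)))
})

setMethod("show", "AffinitySeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("AffinitySeries: %d animals x %d pairs x %d time points\n",
              d[1], d[2], d[3]))
  p <- object@params
  if (length(p))
    cat(sprintf("  sigma = %g s, minDuration = %g s, kappa = %g\n",
                p$sigma, p$minDuration, p$kappa))
})

setMethod("show", "AffinityTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("AffinityTensor: %d (time) x %d (animals) x %d (pairs); %.1f%% observed\n",
              d[1], d[2], d[3], 100 * mean(object@mask)))
})

setMethod("show", "CPModel", function(object) {
  cat(sprintf("CPModel: rank %d, objective %.6g (%d iterations%s)\n",
              object@rank, object@objective, object@iterations,
              if (object@converged) ", converged" else ""))
  cat("  lambda:", paste(signif(object@lambda, 4), collapse = ", "), "\n")
})

setMethod("show", "CommunityPartition", function(object) {
  C <- max(object@labels) + 1L
  cat(sprintf("CommunityPartition: %d nodes in %d communities, dl = %.6g nats\n",
              length(object@labels), C, object@dl))
  cat("  sizes:", paste(tabulate(object@labels + 1L, C), collapse = ", "), "\n")
})
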