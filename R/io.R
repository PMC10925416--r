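#' Write a TraceSet to delimited tables plus a JSON manifest
#'
#' One UTF-8 comma-delimited table per animal (rows = time, first column
#' `time` in seconds, remaining columns one per observed neuron), plus
#' `manifest.json` recording the sampling interval, the shared neuron
#' namespace and each animal's file and missing neurons. Missing neurons are
#' absent columns, not NaN columns.
#'
#' @param traces a [TraceSet].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeTraces <- function(traces, dir) {
  stopifnot2(is(traces, "TraceSet"), "traces must be a TraceSet")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  A <- nAnimals(traces); T <- nTime(traces)
  tt <- (seq_len(T) - 1) * traces@dt
  animals <- vector("list", A)
  for (w in seq_len(A)) {
    obs <- traces@observed[w, ]
    df <- data.frame(time = tt, check.names = FALSE)
    for (j in which(obs)) df[[traces@neuronIds[j]]] <- traces@activity[w, j, ]
    fn <- sprintf("animal_%s.csv", traces@animalIds[w])
    write.csv(df, file.path(dir, fn), row.names = FALSE, quote = FALSE)
    animals[[w]] <- list(id = traces@animalIds[w], file = fn,
                         missing = as.list(traces@neuronIds[!obs]))
  }
  manifest <- list(dt = traces@dt, neurons = as.list(traces@neuronIds),
                   animals = animals)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a TraceSet from a JSON manifest
#'
#' The manifest lists one delimited table per animal, the sampling interval
#' `dt`, and optionally the canonical neuron namespace (`neurons`). When the
#' namespace is absent it is taken as the sorted union of all column headers,
#' so files with permuted column orders yield identical TraceSets. A column
#' not in the namespace is an error naming the animal; a namespace neuron
#' absent from a file is recorded as unobserved for that animal.
#'
#' @param manifestPath path to `manifest.json`.
#' @return a [TraceSet].
#' @export
readTraces <- function(manifestPath) {
  man <- jsonlite::read_json(manifestPath)
  dir <- dirname(manifestPath)
  dt <- as.numeric(man$dt)
  tabs <- lapply(man$animals, function(a) {
    path <- file.path(dir, a$file)
    df <- tryCatch(read.csv(path, check.names = FALSE),
                   error = function(e) stop(sprintf(
                     "failed reading traces for animal '%s': %s", a$id,
                     conditionMessage(e)), call. = FALSE))
    for (cn in setdiff(names(df), "time")) {
      col <- df[[cn]]
      if (!is.numeric(col)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
        stop(sprintf("non-numeric cell in animal '%s', column '%s', row %d",
                     a$id, cn, bad), call. = FALSE)
      }
    }
    df
  })
  ids <- vapply(man$animals, function(a) as.character(a$id), "")
  headers <- lapply(tabs, function(df) setdiff(names(df), "time"))
  if (!is.null(man$neurons)) {
    neurons <- unlist(man$neurons)
    for (w in seq_along(tabs)) {
      extra <- setdiff(headers[[w]], neurons)
      if (length(extra))
        stop(sprintf("animal '%s' has neuron columns not in the manifest namespace: %s",
                     ids[w], paste(extra, collapse = ", ")), call. = FALSE)
    }
  } else {
    neurons <- sort(unique(unlist(headers)))
  }
  Ts <- vapply(tabs, nrow, 0L)
  if (length(unique(Ts)) != 1L)
    stop("animals disagree on the number of time points: ",
         paste(sprintf("%s=%d", ids, Ts), collapse = ", "), call. = FALSE)
  A <- length(tabs); N <- length(neurons); T <- Ts[1]
  act <- array(0, c(A, N, T))
  obs <- matrix(FALSE, A, N)
  for (w in seq_len(A)) {
    for (j in seq_len(N)) {
      cn <- neurons[j]
      if (cn %in% names(tabs[[w]])) {
        act[w, j, ] <- tabs[[w]][[cn]]
        obs[w, j] <- TRUE
      }
    }
    declaredMissing <- unlist(man$animals[[w]]$missing)
    if (length(declaredMissing)) obs[w, neurons %in% declaredMissing] <- FALSE
  }
  new("TraceSet", activity = act, neuronIds = neurons, animalIds = ids,
      observed = obs, dt = dt)
}

#' Write / read a community partition as JSON
#'
#' The JSON carries a `labels` object mapping node id to 0-based community
#' label, plus the description length when known. `readPartition` returns a
#' named integer vector usable wherever labelings are accepted, e.g. as an
#' external method adapter in [runBenchmark()].
#'
#' @param partition a [CommunityPartition] or named integer vector.
#' @param path JSON file path.
#' @return `readPartition`: named integer vector of labels.
#' @export
writePartition <- function(partition, path) {
  if (is(partition, "CommunityPartition")) {
    labels <- partition@labels
    dl <- partition@dl
  } else {
    labels <- partition
    dl <- NULL
  }
  obj <- list(labels = as.list(setNames(as.integer(labels), names(labels))))
  if (!is.null(dl)) obj$dl <- dl
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  obj <- jsonlite::read_json(path)
  labs <- obj$labels %||% obj
  setNames(as.integer(unlist(labs)), names(labs))
}

#' Export one time slice of an affinity series as a weighted edge list
#'
#' Writes tab-separated `(i_id, j_id, weight)` rows for all pairs with
#' positive affinity at time `t` in one animal.
#'
#' @param aff an [AffinitySeries].
#' @param t time index (1-based sample).
#' @param animal animal index.
#' @param path output TSV path.
#' @export
writeAffinitySlice <- function(aff, t, animal, path) {
  v <- aff@values[animal, , t]
  keep <- which(v > 0 & aff@observedPairs[animal, ])
  df <- data.frame(i_id = aff@neuronIds[aff@pairs[keep, 1]],
                   j_id = aff@neuronIds[aff@pairs[keep, 2]],
                   weight = v[keep])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
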