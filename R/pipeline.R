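#' Pipeline configuration
#'
#' Collects every stage parameter, resolvable to/from a single JSON file.
#' `NULL` affinity parameters mean "use the package defaults computed from
#' the data" (see [affinitySeries()]); the resolved values are always
#' written next to the outputs.
#'
#' @param manifest path to a trace manifest (see [readTraces()]), or `NULL`
#'   to simulate.
#' @param simulate a [simSpec()] when simulating input.
#' @param sigma,zeroBand,minDuration,kappa affinity-stage parameters.
#' @param rank,nRestarts,maxIter,tol tensor-stage parameters.
#' @param wMin graph sparsification threshold applied after each affinity
#'   factor is rescaled to peak weight 1.
#' @param burnin,sampling,anneal,betaFinal community-stage MCMC parameters.
#' @param seed master seed; each stage derives its own stream from it.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(manifest = NULL, simulate = NULL, sigma = NULL,
                           zeroBand = NULL, minDuration = NULL, kappa = NULL,
                           rank = 2L, nRestarts = 10L, maxIter = 500L,
                           tol = 1e-7, wMin = 0, burnin = 200L,
                           sampling = 800L, anneal = 200L, betaFinal = 5,
                           seed = 1L) {
  stopifnot2(!is.null(manifest) || !is.null(simulate),
             "provide a manifest path or a simulation spec")
  structure(list(manifest = manifest, simulate = simulate, sigma = sigma,
                 zeroBand = zeroBand, minDuration = minDuration, kappa = kappa,
                 rank = as.integer(rank), nRestarts = as.integer(nRestarts),
                 maxIter = as.integer(maxIter), tol = tol, wMin = wMin,
                 burnin = as.integer(burnin), sampling = as.integer(sampling),
                 anneal = as.integer(anneal), betaFinal = betaFinal,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Run the full inference pipeline
#'
#' Simulate or read traces, compute differential affinities, build and
#' factorize the affinity tensor, then detect communities on each
#' component's affinity graph and write per-component reports. All outputs
#' land under `outdir` together with the fully resolved configuration and a
#' package-version stamp, so every file is regenerable from the config
#' alone. Deterministic given the master seed.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory.
#' @param verbose print per-stage progress to stderr.
#' @return (invisibly) a list with the in-memory artifacts: `traces`,
#'   `truth` (when simulated), `affinity`, `tensor`, `model`, `partitions`,
#'   `reports`.
#' @export
runPipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot2(inherits(config, "pipelineConfig"), "config must come from pipelineConfig()")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- proc.time()[3]
  stamp <- list(package = "dynconn",
                version = as.character(utils::packageVersion("dynconn")),
                rVersion = R.version.string)

  # stage 1a: input
  truth <- NULL
  if (!is.null(config$simulate)) {
    spec <- config$simulate
    spec$seed <- deriveSeed(config$seed, "simulate")
    sim <- simulateTraces(spec)
    traces <- sim$traces
    truth <- sim$truth
    writeTraces(traces, file.path(outdir, "traces"))
    jsonlite::write_json(
      list(circuits = lapply(truth$circuits, unclass), overlaps = truth$overlaps),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    say("[simulate] %d animals x %d neurons x %d samples", nAnimals(traces),
        nNeurons(traces), nTime(traces))
  } else {
    traces <- readTraces(config$manifest)
    say("[read] %s", config$manifest)
  }

  # stage 1b: affinities
  aff <- affinitySeries(traces, config$sigma, config$zeroBand,
                        config$minDuration, config$kappa)
  say("[affinity] %d pairs, params: sigma=%g zeroBand=%s minDuration=%g kappa=%g",
      nrow(aff@pairs), aff@params$sigma,
      paste(signif(aff@params$zeroBand, 3), collapse = "/"),
      aff@params$minDuration, aff@params$kappa)

  # stage 2: tensor factorization
  tensor <- buildTensor(aff)
  model <- halsFit(tensor, config$rank, nRestarts = config$nRestarts,
                   seed = deriveSeed(config$seed, "factorize"),
                   maxIter = config$maxIter, tol = config$tol)
  say("[factorize] rank %d, objective %.6g, %d iterations", model@rank,
      model@objective, model@iterations)
  writeCPModel(model, file.path(outdir, "cp_model"))

  # stage 3: per-component communities
  partitions <- vector("list", model@rank)
  reports <- vector("list", model@rank)
  for (r in seq_len(model@rank)) {
    fa <- model@affinity[, r]
    if (max(fa) > 0) fa <- fa / max(fa)  # rescale to peak weight 1
    A <- factorToMatrix(fa, ids = model@neuronIds)
    g <- graphFromMatrix(A, wMin = config$wMin)
    part <- mcmcPartition(g, seed = deriveSeed(config$seed, paste0("communities-", r)),
                          burnin = config$burnin, sampling = config$sampling,
                          anneal = config$anneal, betaFinal = config$betaFinal)
    partitions[[r]] <- part
    reports[[r]] <- communityReport(g, part, model, r, traces)
    writePartition(part, file.path(outdir, sprintf("partition_component%d.json", r)))
    writeGraph(g, file.path(outdir, sprintf("graph_component%d.tsv", r)))
    say("[communities] component %d: %d communities, dl %.6g",
        r, max(part@labels) + 1L, part@dl)
  }

  # resolved config + stamp: every run is regenerable from this file
  resolved <- unclass(config)
  if (!is.null(config$simulate)) {
    sim <- unclass(config$simulate)
    sim$circuits <- lapply(sim$circuits, unclass)
    resolved$simulate <- sim
  }
  resolved$affinityParams <- aff@params
  resolved$stamp <- stamp
  resolved$elapsedSeconds <- unname(proc.time()[3] - t0)
  jsonlite::write_json(resolved, file.path(outdir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  reportOut <- lapply(reports, function(rep) list(
    communities = rep$communities, window = rep$window, topAnimals = rep$topAnimals))
  jsonlite::write_json(reportOut, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %.1f s", resolved$elapsedSeconds)
  invisible(list(traces = traces, truth = truth, affinity = aff,
                 tensor = tensor, model = model, partitions = partitions,
                 reports = reports))
}

#' Persist a CP model as delimited factor tables plus JSON metadata
#'
#' @param model a [CPModel].
#' @param dir output directory.
#' @export
writeCPModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- factorMatrices(model)
  for (nm in names(f)) {
    df <- as.data.frame(f[[nm]])
    names(df) <- paste0("component", seq_len(model@rank))
    write.csv(df, file.path(dir, paste0("factor_", nm, ".csv")), row.names = FALSE)
  }
  meta <- list(rank = model@rank, lambda = model@lambda,
               objective = model@objective, objHistory = model@objHistory,
               seed = model@seed, iterations = model@iterations,
               converged = model@converged, neuronIds = model@neuronIds,
               animalIds = model@animalIds)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from JSON
#'
#' Inverse of the `config_resolved.json` written by [runPipeline()] (the
#' resolved affinity parameters and stamp are ignored on the way in).
#'
#' @param path JSON path.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  obj <- jsonlite::read_json(path)
  sim <- NULL
  if (!is.null(obj$simulate)) {
    s <- obj$simulate
    circuits <- lapply(s$circuits, function(ci)
      plantedCircuit(unlist(ci$members), unlist(ci$window),
                     if (is.null(ci$animals)) NULL else unlist(ci$animals),
                     ci$amplitude, unlist(ci$polarity)))
    sim <- simSpec(s$nNeurons, s$nAnimals, s$nTimepoints, circuits,
                   noiseSd = s$noiseSd, baselineDriftSd = s$baselineDriftSd,
                   dt = s$dt, driveShape = s$driveShape %||% "triangle",
                   seed = s$seed)
  }
  pipelineConfig(manifest = obj$manifest, simulate = sim, sigma = obj$sigma,
                 zeroBand = if (is.null(obj$zeroBand)) NULL else unlist(obj$zeroBand),
                 minDuration = obj$minDuration, kappa = obj$kappa,
                 rank = obj$rank, nRestarts = obj$nRestarts,
                 maxIter = obj$maxIter, tol = obj$tol, wMin = obj$wMin,
                 burnin = obj$burnin, sampling = obj$sampling,
                 anneal = obj$anneal, betaFinal = obj$betaFinal,
                 seed = obj$seed)
}
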