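#' Describe a planted transient circuit
#'
#' A circuit is a set of neurons sharing one smooth latent drive over a time
#' window, in a subset of animals. Members may carry opposite polarities: a
#' member with polarity -1 mirrors the drive, emulating inhibitory coupling.
#' The differential affinity measure is sign-invariant, so such members must
#' still be linked downstream.
#'
#' @param members integer vector of neuron indices (1-based), at least 2.
#' @param window half-open sample interval `c(t0, t1)`, 1-based: samples
#'   `t0 .. t1-1` are inside the window.
#' @param animals integer vector of participating animal indices; `NULL`
#'   means all animals.
#' @param amplitude positive peak amplitude of the drive.
#' @param polarity per-member signs in {-1, +1}; by default the last member
#'   gets -1 so every circuit exercises sign-invariance.
#' @return a `plantedCircuit` list.
#' @export
plantedCircuit <- function(members, window, animals = NULL, amplitude = 1,
                           polarity = NULL) {
  members <- as.integer(members)
  stopifnot2(length(members) >= 2L && !anyDuplicated(members),
             "a circuit needs >= 2 distinct members")
  stopifnot2(length(window) == 2L && window[1] < window[2],
             "window must be c(t0, t1) with t0 < t1")
  if (is.null(polarity)) polarity <- c(rep(1, length(members) - 1L), -1)
  stopifnot2(length(polarity) == length(members) && all(abs(polarity) == 1),
             "polarity must be +/-1 per member")
  stopifnot2(is.numeric(amplitude) && amplitude > 0, "amplitude must be positive")
  structure(list(members = members, window = as.integer(window),
                 animals = if (is.null(animals)) NULL else as.integer(animals),
                 amplitude = amplitude, polarity = polarity),
            class = "plantedCircuit")
}

#' Specify a synthetic multi-animal trace simulation
#'
#' @param nNeurons,nAnimals,nTimepoints problem dimensions.
#' @param circuits list of [plantedCircuit()] objects.
#' @param noiseSd standard deviation of i.i.d. additive observation noise.
#' @param baselineDriftSd per-sample standard deviation of the slow baseline
#'   random walk each neuron follows outside (and underneath) circuit
#'   activity; 0 gives flat baselines.
#' @param dt sampling interval in seconds.
#' @param driveShape latent-drive shape: `"triangle"` (one monotone rise and
#'   fall per window, the default) or `"bumps"` (a double-exponential bump
#'   train with calcium-like kinetics).
#' @param seed integer RNG seed; the whole simulation is deterministic given
#'   the spec.
#' @return a `simSpec` list, validated against the dimensions.
#' @export
simSpec <- function(nNeurons, nAnimals, nTimepoints, circuits = list(),
                    noiseSd = 0.05, baselineDriftSd = 0, dt = 0.25,
                    driveShape = c("triangle", "bumps"), seed = 1L) {
  driveShape <- match.arg(driveShape)
  stopifnot2(nNeurons >= 2L, "need at least 2 neurons")
  stopifnot2(nAnimals >= 1L, "need at least 1 animal")
  stopifnot2(nTimepoints >= 3L, "need at least 3 time points")
  stopifnot2(noiseSd >= 0 && baselineDriftSd >= 0, "noise parameters must be >= 0")
  for (circ in circuits) {
    stopifnot2(inherits(circ, "plantedCircuit"), "circuits must be plantedCircuit objects")
    stopifnot2(all(circ$members >= 1L & circ$members <= nNeurons),
               "circuit members out of range")
    if (circ$window[1] < 1L || circ$window[2] > nTimepoints + 1L)
      stop("circuit window outside the time axis", call. = FALSE)
    if (!is.null(circ$animals))
      stopifnot2(all(circ$animals >= 1L & circ$animals <= nAnimals),
                 "circuit animals out of range")
  }
  structure(list(nNeurons = as.integer(nNeurons), nAnimals = as.integer(nAnimals),
                 nTimepoints = as.integer(nTimepoints), circuits = circuits,
                 noiseSd = noiseSd, baselineDriftSd = baselineDriftSd,
                 dt = dt, driveShape = driveShape, seed = as.integer(seed)),
            class = "simSpec")
}

# latent circuit drive over a window, peak-normalized to 1.
#   triangle: one monotone rise to mid-window and monotone fall back —
#     constant |slope|, the canonical "shared monotonic excursion" a
#     transient circuit shows during a stimulus epoch;
#   bumps: a train of double-exponential bumps (rise ~1 s, decay ~5 s,
#     calcium-indicator-like kinetics), onsets every `spacing` seconds,
#     per-bump amplitudes jittered.
latentDrive <- function(len, dt, shape = c("triangle", "bumps"),
                        rise = 1, decay = 5, spacing = 8) {
  shape <- match.arg(shape)
  if (shape == "triangle") {
    x <- seq_len(len) / len
    return(1 - abs(2 * x - 1))
  }
  tt <- (seq_len(len) - 1) * dt
  onsets <- seq(0, max(0, (len - 1) * dt - rise), by = spacing)
  drive <- numeric(len)
  for (on in onsets) {
    amp <- runif(1, 0.7, 1.3)
    tau <- tt - on
    b <- ifelse(tau >= 0, (1 - exp(-pmax(tau, 0) / rise)) * exp(-pmax(tau, 0) / decay), 0)
    drive <- drive + amp * b
  }
  if (max(drive) > 0) drive <- drive / max(drive)
  drive
}

#' Simulate multi-animal traces with planted transient circuits
#'
#' Within each circuit's window, member neurons of the participating animals
#' share a common smooth latent drive (scaled by amplitude and per-member
#' polarity); elsewhere neurons follow independent low-amplitude baseline
#' drift. Ground truth (memberships, windows, animal sets) is returned for
#' downstream evaluation.
#'
#' @param spec a [simSpec()].
#' @return list with elements `traces` (a [TraceSet]) and `truth` (circuit
#'   ground truth: `circuits`, plus `overlaps`, pairs of circuits sharing a
#'   neuron while their windows overlap).
#' @export
simulateTraces <- function(spec) {
  stopifnot2(inherits(spec, "simSpec"), "spec must come from simSpec()")
  set.seed(spec$seed)
  A <- spec$nAnimals; N <- spec$nNeurons; T <- spec$nTimepoints
  act <- array(0, c(A, N, T))
  if (spec$baselineDriftSd > 0) {
    for (w in seq_len(A)) {
      steps <- matrix(rnorm(N * T, 0, spec$baselineDriftSd), N, T)
      drift <- t(apply(steps, 1, cumsum))
      act[w, , ] <- gaussianSmoothRows(drift, 2 / spec$dt)
    }
  }
  for (circ in spec$circuits) {
    t0 <- circ$window[1]; t1 <- circ$window[2]
    drive <- latentDrive(t1 - t0, spec$dt, spec$driveShape) * circ$amplitude
    ws <- circ$animals %||% seq_len(A)
    for (w in ws)
      for (k in seq_along(circ$members))
        act[w, circ$members[k], t0:(t1 - 1L)] <-
          act[w, circ$members[k], t0:(t1 - 1L)] + circ$polarity[k] * drive
  }
  if (spec$noiseSd > 0)
    act <- act + array(rnorm(length(act), 0, spec$noiseSd), dim(act))
  traces <- new("TraceSet", activity = act,
                neuronIds = sprintf("n%03d", seq_len(N)),
                animalIds = sprintf("w%02d", seq_len(A)),
                observed = matrix(TRUE, A, N), dt = spec$dt)
  truth <- list(circuits = spec$circuits, overlaps = circuitOverlaps(spec$circuits))
  list(traces = traces, truth = truth)
}

# pairs of circuits that share a neuron while their windows intersect
circuitOverlaps <- function(circuits) {
  out <- list()
  if (length(circuits) < 2L) return(out)
  for (a in seq_len(length(circuits) - 1L))
    for (b in (a + 1L):length(circuits)) {
      ca <- circuits[[a]]; cb <- circuits[[b]]
      shared <- intersect(ca$members, cb$members)
      winOverlap <- ca$window[1] < cb$window[2] && cb$window[1] < ca$window[2]
      if (length(shared) && winOverlap)
        out[[length(out) + 1L]] <- list(circuits = c(a, b), neurons = shared)
    }
  out
}

#' Ground-truth community labels from planted circuits
#'
#' Neurons belonging to circuit k get label k; neurons in no circuit get
#' label 0 (background). Neurons in several circuits get the first one.
#'
#' @param truth the ground-truth list from [simulateTraces()].
#' @param nNeurons total neuron count.
#' @return integer label vector of length `nNeurons`.
#' @export
groundTruthLabels <- function(truth, nNeurons) {
  lab <- integer(nNeurons)
  for (k in rev(seq_along(truth$circuits)))
    lab[truth$circuits[[k]]$members] <- k
  lab
}
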