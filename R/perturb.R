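#' Enumerate 1- and 2-gene clamp signals
#'
#' All N singletons followed by all C(N, 2) unordered pairs, in stable
#' index order (for N = 26 this is 351 signals).
#'
#' @param topology a [GRNTopology-class].
#' @return list of character vectors (length 1 or 2).
#' @export
enumerateSignals <- function(topology) {
  nd <- geneNames(topology)
  if (length(nd) < 1) stop("topology has no nodes")
  singles <- lapply(nd, identity)
  pairs <- if (length(nd) >= 2) {
    cmb <- utils::combn(nd, 2)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else list()
  c(singles, pairs)
}

#' Protocol configuration for ODE perturbation runs
#'
#' @param tSignal duration of the clamped (and, if noisy, noise-carrying)
#'   signal phase, in time units.
#' @param tRelax duration of the unclamped deterministic relaxation phase.
#' @param h Euler step size.
#' @param knnK neighbours used by the KNN state classifier.
#' @param nTrials independent stochastic repeats per model/signal.
#' @param recordEvery trajectory sampling interval in time units (0 = do not
#'   record).
#' @return a list of class `ProtocolConfig`.
#' @export
protocolConfig <- function(tSignal = 500, tRelax = 50, h = 0.1, knnK = 25,
                           nTrials = 1, recordEvery = 0) {
  stopifnot(tSignal >= 0, tRelax >= 0, h > 0, knnK >= 1, nTrials >= 1,
            recordEvery >= 0)
  structure(list(tSignal = tSignal, tRelax = tRelax, h = h,
                 knnK = as.integer(knnK), nTrials = as.integer(nTrials),
                 recordEvery = recordEvery),
            class = "ProtocolConfig")
}

#' One exact Ornstein-Uhlenbeck update
#'
#' `U(t + h) = U(t) e^(-h/tau) + Dg sqrt(1 - e^(-2h/tau)) z`, where `Dg` is
#' the stationary standard deviation and `z` a standard normal draw. Iterated
#' from any start, the process has stationary sd `Dg` and lag-h
#' autocorrelation `e^(-h/tau)`.
#'
#' @param U current noise value.
#' @param h time step (> 0).
#' @param tau correlation time (> 0).
#' @param Dg stationary standard deviation.
#' @param z standard normal draw (default: one fresh draw).
#' @return updated noise value.
#' @export
ouStep <- function(U, h, tau, Dg, z = stats::rnorm(length(U))) {
  stopifnot(h > 0, tau > 0)
  U * exp(-h / tau) + Dg * sqrt(1 - exp(-2 * h / tau)) * z
}

# Reference set used by the KNN classifier: processed matrix (states x genes),
# labels and the shared preprocessing transform. Accepts a GRNStateEnsemble.
.asReference <- function(reference) {
  if (methods::is(reference, "GRNStateEnsemble")) {
    list(processed = t(SummarizedExperiment::assay(reference, "processed")),
         labels = stateLabels(reference),
         transform = stateTransform(reference))
  } else reference
}

#' Classify a state by k-nearest neighbours
#'
#' Transforms the raw state with the ensemble's stored log1p/standardize
#' transform and takes the majority label among its `k` nearest reference
#' states (Euclidean distance). Exact label ties are broken toward "M" — a
#' fixed, documented rule rather than platform-dependent randomness.
#'
#' @param state raw-scale expression vector (or matrix of rows to classify).
#' @param reference a [GRNStateEnsemble-class] or a list with elements
#'   `processed`, `labels`, `transform`.
#' @param k neighbour count (must not exceed the reference size).
#' @return character vector of labels.
#' @export
classifyState <- function(state, reference, k = 25) {
  ref <- .asReference(reference)
  nRef <- nrow(ref$processed)
  if (k > nRef) stop("k = ", k, " exceeds reference size ", nRef)
  q <- applyTransform(state, ref$transform)
  if (is.null(dim(q))) q <- matrix(q, 1)
  vapply(seq_len(nrow(q)), function(r) {
    d2 <- colSums((t(ref$processed) - q[r, ])^2)
    nn <- order(d2)[seq_len(k)]
    tb <- table(ref$labels[nn])
    top <- names(tb)[tb == max(tb)]
    if (length(top) > 1 && "M" %in% top) "M" else top[1]
  }, character(1))
}

# Per-gene OU stationary sd: D scaled by the mean expression of each gene
# across the model's known steady states.
.noiseScale <- function(model, D) {
  if (D <= 0) return(rep(0, ncol(model$states)))
  D * colMeans(model$states)
}

#' Run one clamped perturbation protocol on an ODE model
#'
#' Starting from one of the model's steady states, the signal genes are held
#' bit-identical to their expression in the target steady state for
#' `protocol$tSignal` time units while all other genes evolve under the
#' model ODEs plus (optionally) per-gene OU noise added to the derivative.
#' The clamp and noise are then removed and the system relaxes
#' deterministically for `protocol$tRelax` units before the final state is
#' classified by KNN against the unperturbed ensemble.
#'
#' @param model a bistable model from [bistableModels()].
#' @param topology the generating [GRNTopology-class].
#' @param signalGenes character vector of 1-2 genes to clamp (the engine
#'   accepts any number, including none for noise-only controls).
#' @param reference classification reference (usually the
#'   [GRNStateEnsemble-class] itself).
#' @param startLabel which steady state to start from ("E" or "M").
#' @param targetLabel the state supplying the clamp values (default: the
#'   other label).
#' @param D noise scale: stationary OU sd per unit mean expression.
#' @param tau OU correlation time.
#' @param protocol a [protocolConfig()].
#' @return list with `model_id`, `signal`, `start_label`, `end_label`,
#'   `transitioned`, `final`, and when `protocol$recordEvery > 0` also
#'   `trajectory` (time x genes) and `time`.
#' @export
runPerturbation <- function(model, topology, signalGenes, reference,
                            startLabel = "E", targetLabel = NULL,
                            D = 0, tau = 10, protocol = protocolConfig()) {
  nd <- geneNames(topology)
  if (is.null(targetLabel)) targetLabel <- setdiff(c("E", "M"), startLabel)
  start <- model$states[startLabel, ]
  target <- model$states[targetLabel, ]
  idx <- integer(0); vals <- numeric(0)
  if (length(signalGenes)) {
    idx <- match(signalGenes, nd)
    if (anyNA(idx)) stop("signal gene not in topology: ",
                         paste(signalGenes[is.na(idx)], collapse = ", "))
    vals <- as.numeric(target[idx])
  }
  ei <- .edgeIdx(model$params, topology)
  res <- cpp_perturb_run(as.numeric(start), as.numeric(model$params$G),
                         as.numeric(model$params$k), ei$esrc, ei$etgt,
                         ei$elam, ei$ethr, ei$ehill, protocol$h,
                         protocol$tSignal, protocol$tRelax,
                         idx - 1L, vals, .noiseScale(model, D), tau,
                         protocol$recordEvery)
  fin <- stats::setNames(res$final, nd)
  endLabel <- classifyState(fin, reference, k = protocol$knnK)
  out <- list(model_id = model$model_id, signal = signalGenes,
              start_label = startLabel, end_label = endLabel,
              transitioned = (endLabel == targetLabel) &&
                             (startLabel != targetLabel),
              final = fin)
  if (protocol$recordEvery > 0) {
    colnames(res$trajectory) <- nd
    out$trajectory <- res$trajectory
    out$time <- res$time
  }
  out
}

#' Signal efficacy across a bistable ensemble
#'
#' Starts every model in its E state, applies the clamp signal (with optional
#' OU noise) and reports the percentage of models that end in the M state,
#' averaged over `protocol$nTrials` repeats.
#'
#' @param models list of bistable models from [bistableModels()].
#' @inheritParams runPerturbation
#' @param signalGenes genes to clamp at their M-state values.
#' @return percentage in \[0, 100\].
#' @export
signalEfficacy <- function(models, topology, signalGenes, reference,
                           D = 0, tau = 10, protocol = protocolConfig()) {
  if (length(models) == 0) stop("empty model set")
  pct <- vapply(seq_len(protocol$nTrials), function(trial) {
    hits <- vapply(models, function(m) {
      runPerturbation(m, topology, signalGenes, reference,
                      startLabel = "E", D = D, tau = tau,
                      protocol = protocol)$transitioned
    }, logical(1))
    100 * mean(hits)
  }, numeric(1))
  mean(pct)
}

#' Screen many signals across the bistable ensemble
#'
#' @inheritParams signalEfficacy
#' @param signals list of character vectors, e.g. from [enumerateSignals()].
#' @return data.frame with columns `gene_1`, `gene_2` (NA for singletons),
#'   `n_models`, `emt_percent`.
#' @export
screenSignals <- function(models, topology, signals, reference,
                          D = 0, tau = 10, protocol = protocolConfig()) {
  rows <- lapply(signals, function(sg) {
    data.frame(gene_1 = sg[1], gene_2 = if (length(sg) > 1) sg[2] else NA,
               n_models = length(models),
               emt_percent = signalEfficacy(models, topology, sg, reference,
                                            D = D, tau = tau,
                                            protocol = protocol),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spontaneous (noise-only) transition rates
#'
#' Control runs with noise but no clamp: for each noise level, the fraction
#' of models switching E to M and M to E over the same signal/relaxation
#' window as the perturbation protocol.
#'
#' @inheritParams signalEfficacy
#' @param noiseLevels numeric vector of noise scales D.
#' @return data.frame with columns `D`, `emt_percent`, `met_percent`.
#' @export
spontaneousRates <- function(models, topology, noiseLevels, reference,
                             tau = 10, protocol = protocolConfig()) {
  rows <- lapply(noiseLevels, function(D) {
    emt <- signalEfficacy(models, topology, character(0), reference,
                          D = D, tau = tau, protocol = protocol)
    met <- vapply(models, function(m) {
      runPerturbation(m, topology, character(0), reference,
                      startLabel = "M", D = D, tau = tau,
                      protocol = protocol)$transitioned
    }, logical(1))
    data.frame(D = D, emt_percent = emt, met_percent = 100 * mean(met))
  })
  do.call(rbind, rows)
}

#' Time of first arrival in the target state
#'
#' Classifies every sampled trajectory point and returns the earliest sampled
#' time labelled with the target; `NA` if the trajectory never reaches it.
#'
#' @param result a [runPerturbation()] result with a recorded trajectory.
#' @param reference classification reference.
#' @param targetLabel label to detect (default "M").
#' @param k KNN neighbour count.
#' @return numeric time, or `NA` if the target is never reached.
#' @export
transitionTime <- function(result, reference, targetLabel = "M", k = 25) {
  if (is.null(result$trajectory))
    stop("result carries no trajectory; rerun with protocol recordEvery > 0")
  lab <- classifyState(result$trajectory, reference, k = k)
  hit <- which(lab == targetLabel)
  if (length(hit)) result$time[hit[1]] else NA_real_
}

#' Minimum noise level enabling a transition under a fixed clamp
#'
#' Scans an increasing grid of noise scales; for each, runs `nTrials`
#' clamped stochastic simulations from `fromState` and checks whether any
#' run ends (still clamped, before relaxation) nearer to `toState` than to
#' `fromState` in log1p coordinates. Returns the smallest grid value with at
#' least one such transition.
#'
#' @param model a bistable model (supplies the parameters).
#' @param topology the generating [GRNTopology-class].
#' @param clampValues named numeric vector: genes held fixed (the signal).
#' @param fromState,toState raw-scale steady states of the clamped system.
#' @param DGrid increasing numeric grid of noise scales.
#' @param tau OU correlation time.
#' @param protocol a [protocolConfig()]; only the signal phase is used.
#' @param nTrials stochastic repeats per grid point.
#' @return list with `D` (smallest enabling noise, or `NA`) and `nTransitions`
#'   per grid value.
#' @export
noiseThresholdScan <- function(model, topology, clampValues, fromState,
                               toState, DGrid, tau = 10,
                               protocol = protocolConfig(), nTrials = 5) {
  if (length(DGrid) == 0) stop("empty noise grid")
  nd <- geneNames(topology)
  idx <- match(names(clampValues), nd)
  if (anyNA(idx)) stop("clamp gene not in topology")
  ei <- .edgeIdx(model$params, topology)
  counts <- integer(length(DGrid))
  found <- NA_real_
  for (gi in seq_along(DGrid)) {
    D <- DGrid[gi]
    for (tr in seq_len(nTrials)) {
      res <- cpp_perturb_run(as.numeric(fromState), as.numeric(model$params$G),
                             as.numeric(model$params$k), ei$esrc, ei$etgt,
                             ei$elam, ei$ethr, ei$ehill, protocol$h,
                             protocol$tSignal, 0, idx - 1L,
                             as.numeric(clampValues[names(clampValues)]),
                             .noiseScale(model, D), tau, 0)
      dTo <- sum((log1p(res$final) - log1p(toState))^2)
      dFrom <- sum((log1p(res$final) - log1p(fromState))^2)
      if (dTo < dFrom) counts[gi] <- counts[gi] + 1L
    }
    if (is.na(found) && counts[gi] > 0) found <- D
  }
  list(D = found, nTransitions = stats::setNames(counts, DGrid))
}
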