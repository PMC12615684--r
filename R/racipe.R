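#' Configuration for the randomized ODE ensemble
#'
#' @param nModels number of randomized parameter sets.
#' @param nICs random initial conditions integrated per model.
#' @param dedupDecimals steady states equal after rounding their
#'   log1p-transformed values to this many decimals are collapsed.
#' @param h fixed Euler step size (time units).
#' @param tMax maximum integration time per trajectory.
#' @param tol convergence tolerance on the infinity norm of the derivative.
#' @param gRange,kRange uniform sampling ranges for the maximum production
#'   and degradation rates.
#' @param hillRange inclusive integer range of Hill coefficients.
#' @param lambdaActRange,lambdaInhRange uniform ranges of the fold change for
#'   activating and inhibiting edges.
#' @param thresholdRange thresholds are drawn uniformly from
#'   `thresholdRange * medianLevel` (the half-functional convention).
#' @param medianLevel typical expression scale used to centre the threshold
#'   draw; the default 91.8 is the median of the unregulated level `G/k`
#'   under the default rate ranges.
#' @param icRange initial conditions are log-uniform between `icRange[1]` and
#'   `icRange[2] * G/k` per gene.
#' @param dedupOnRaw if `TRUE`, deduplication rounds raw rather than
#'   log1p-transformed values.
#' @return a list of class `EnsembleConfig`.
#' @export
ensembleConfig <- function(nModels = 1000, nICs = 200, dedupDecimals = 2,
                           h = 0.1, tMax = 200, tol = 1e-6,
                           gRange = c(1, 100), kRange = c(0.1, 1),
                           hillRange = c(1L, 6L),
                           lambdaActRange = c(1, 100),
                           lambdaInhRange = c(0.01, 1),
                           thresholdRange = c(0.02, 1.98),
                           medianLevel = 91.8,
                           icRange = c(1e-2, 1),
                           dedupOnRaw = FALSE) {
  stopifnot(nModels >= 1, nICs >= 1, dedupDecimals >= 0, h > 0, tMax > 0,
            tol > 0)
  structure(list(nModels = nModels, nICs = nICs,
                 dedupDecimals = as.integer(dedupDecimals), h = h, tMax = tMax,
                 tol = tol, gRange = gRange, kRange = kRange,
                 hillRange = as.integer(hillRange),
                 lambdaActRange = lambdaActRange,
                 lambdaInhRange = lambdaInhRange,
                 thresholdRange = thresholdRange, medianLevel = medianLevel,
                 icRange = icRange, dedupOnRaw = dedupOnRaw),
            class = "EnsembleConfig")
}

#' Estimate per-gene median expression levels
#'
#' Half-functional threshold support: for each gene, the median of its
#' steady-state level is estimated by Monte Carlo over the parameter ranges,
#' applying one pass of shifted-Hill factors from its regulators (whose own
#' levels are drawn from the unregulated `G/k` distribution). Genes with many
#' inhibitors therefore receive proportionally lower thresholds on their
#' outgoing edges, keeping each regulatory link about half functional across
#' the ensemble.
#'
#' @param topology a [GRNTopology-class].
#' @param config an [ensembleConfig()].
#' @param nDraws Monte Carlo draws per gene.
#' @return named numeric vector of median levels.
#' @export
estimateMedianLevels <- function(topology, config = ensembleConfig(),
                                 nDraws = 2000) {
  nd <- geneNames(topology)
  ed <- edgeTable(topology)
  M0 <- config$medianLevel
  M <- stats::setNames(rep(M0, length(nd)), nd)
  hillSeq <- seq(config$hillRange[1], config$hillRange[2])
  for (b in nd) {
    inc <- ed[ed$target == b, , drop = FALSE]
    lvl <- stats::runif(nDraws, config$gRange[1], config$gRange[2]) /
           stats::runif(nDraws, config$kRange[1], config$kRange[2])
    for (e in seq_len(nrow(inc))) {
      act <- inc$sign[e] > 0
      lam <- if (act)
        stats::runif(nDraws, config$lambdaActRange[1], config$lambdaActRange[2])
      else
        stats::runif(nDraws, config$lambdaInhRange[1], config$lambdaInhRange[2])
      n <- sample(hillSeq, nDraws, replace = TRUE)
      B0 <- stats::runif(nDraws, config$thresholdRange[1],
                         config$thresholdRange[2]) * M0
      C <- stats::runif(nDraws, config$gRange[1], config$gRange[2]) /
           stats::runif(nDraws, config$kRange[1], config$kRange[2])
      lvl <- lvl * (lam + (1 - lam) / (1 + (C / B0)^n)) / lam
    }
    M[b] <- stats::median(lvl)
  }
  M
}

#' Draw one randomized parameter set for a topology
#'
#' Per gene, a maximum production rate `G ~ U(1, 100)` and degradation rate
#' `k ~ U(0.1, 1)`; per edge, an integer Hill coefficient `n ~ U{1..6}`, a
#' fold change `lambda ~ U(1, 100)` for activation or `U(0.01, 1)` for
#' inhibition, and a half-functional threshold
#' `B0 ~ U(0.02, 1.98) * M_source`, where `M_source` is the regulator's
#' estimated median level (see [estimateMedianLevels()]), so that regulator
#' levels are comparable to their thresholds across the ensemble.
#'
#' @param topology a [GRNTopology-class].
#' @param config an [ensembleConfig()].
#' @param medianLevels optional named vector from [estimateMedianLevels()];
#'   if `NULL`, the flat `config$medianLevel` constant is used for every
#'   gene.
#' @return list of class `RacipeParams` with elements `G`, `k` (named
#'   numeric) and `edges` (the edge table extended with `lambda`,
#'   `threshold`, `hill`).
#' @export
sampleParameters <- function(topology, config = ensembleConfig(),
                             medianLevels = NULL) {
  nd <- geneNames(topology)
  ed <- edgeTable(topology)
  G <- stats::setNames(stats::runif(length(nd), config$gRange[1], config$gRange[2]), nd)
  k <- stats::setNames(stats::runif(length(nd), config$kRange[1], config$kRange[2]), nd)
  nE <- nrow(ed)
  if (nE) {
    act <- ed$sign > 0
    lambda <- numeric(nE)
    lambda[act] <- stats::runif(sum(act), config$lambdaActRange[1],
                                config$lambdaActRange[2])
    lambda[!act] <- stats::runif(sum(!act), config$lambdaInhRange[1],
                                 config$lambdaInhRange[2])
    srcMed <- if (is.null(medianLevels)) rep(config$medianLevel, nE)
              else medianLevels[ed$source]
    threshold <- stats::runif(nE, config$thresholdRange[1],
                              config$thresholdRange[2]) * srcMed
    hill <- sample(seq(config$hillRange[1], config$hillRange[2]), nE,
                   replace = TRUE)
    ed <- cbind(ed, data.frame(lambda = lambda, threshold = threshold,
                               hill = as.integer(hill)))
  } else {
    ed <- cbind(ed, data.frame(lambda = numeric(0), threshold = numeric(0),
                               hill = integer(0)))
  }
  structure(list(G = G, k = k, edges = ed), class = "RacipeParams")
}

# Edge parameter vectors in the 0-based index form used by the C++ core.
.edgeIdx <- function(params, topology) {
  nd <- geneNames(topology)
  ed <- params$edges
  list(esrc = match(ed$source, nd) - 1L, etgt = match(ed$target, nd) - 1L,
       elam = as.numeric(ed$lambda), ethr = as.numeric(ed$threshold),
       ehill = as.integer(ed$hill))
}

#' Right-hand side of the regulatory ODE system
#'
#' For a gene A with regulators B_i, the production is the maximum rate
#' scaled by shifted-Hill factors,
#' `G_A / prod(lambda_i) * prod(lambda_i + (1 - lambda_i) /
#' (1 + (B_i / B0_i)^n_i))`, minus linear degradation `k_A * A`. An
#' unregulated gene relaxes to `G_A / k_A`.
#'
#' @param expression non-negative expression vector in node order.
#' @param params a `RacipeParams` from [sampleParameters()].
#' @param topology the generating [GRNTopology-class].
#' @return derivative vector.
#' @export
racipeRHS <- function(expression, params, topology) {
  if (any(expression < 0)) stop("expression must be non-negative")
  ei <- .edgeIdx(params, topology)
  stats::setNames(cpp_rhs(as.numeric(expression), as.numeric(params$G),
                          as.numeric(params$k), ei$esrc, ei$etgt, ei$elam,
                          ei$ethr, ei$ehill),
                  geneNames(topology))
}

# log-uniform initial conditions between icRange[1] and icRange[2] * G/k.
.randomICs <- function(params, n, config) {
  lo <- config$icRange[1]
  hi <- pmax(config$icRange[2] * params$G / params$k, lo * 10)
  N <- length(params$G)
  u <- matrix(stats::runif(n * N), n, N)
  sweep(exp(sweep(u, 2, log(hi / lo), `*`)), 2, lo, `*`)
}

.dedupStates <- function(states, config) {
  key <- if (config$dedupOnRaw) round(states, config$dedupDecimals)
         else round(log1p(states), config$dedupDecimals)
  keep <- !duplicated(apply(key, 1, paste, collapse = ","))
  states[keep, , drop = FALSE]
}

#' Enumerate the stable steady states of one model
#'
#' Integrates the model from `config$nICs` random initial conditions
#' (log-uniform over the reachable expression range) with fixed-step Euler
#' until the derivative infinity norm falls below `config$tol` or `tMax` is
#' reached. Non-converged trajectories are excluded and counted. Near
#' identical endpoints are collapsed by rounding (by default on the log1p
#' scale) to `config$dedupDecimals` decimals.
#'
#' @inheritParams racipeRHS
#' @param config an [ensembleConfig()].
#' @return list with `states` (matrix, states in rows, gene columns),
#'   `nConverged`, `nDiverged`.
#' @export
findSteadyStates <- function(params, topology, config = ensembleConfig()) {
  ei <- .edgeIdx(params, topology)
  X0 <- .randomICs(params, config$nICs, config)
  res <- cpp_find_states(X0, as.numeric(params$G), as.numeric(params$k),
                         ei$esrc, ei$etgt, ei$elam, ei$ethr, ei$ehill,
                         config$h, config$tMax, config$tol, 10L)
  ok <- res$converged
  states <- res$states[ok, , drop = FALSE]
  colnames(states) <- geneNames(topology)
  states <- if (nrow(states)) .dedupStates(states, config)
            else states
  list(states = states, nConverged = sum(ok), nDiverged = sum(!ok))
}

#' Preprocess pooled steady states
#'
#' Applies `log(1 + x)` entrywise, then standardizes each gene column across
#' all pooled states (sample standard deviation). Zero-variance genes are
#' mapped to 0 with a warning. The returned transform (per-gene mean and sd
#' on the log1p scale) is reused to place trajectories and final states in
#' the same coordinates.
#'
#' @param states matrix of raw steady states (states in rows, genes in
#'   columns).
#' @return list with `processed` (matrix) and `transform`
#'   (list with `mu`, `sd`).
#' @export
preprocessStates <- function(states) {
  lg <- log1p(states)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  zero <- !is.finite(sd) | sd == 0
  if (any(zero)) {
    warning("zero-variance gene(s) standardized to 0: ",
            paste(colnames(states)[zero], collapse = ", "))
    sd[zero] <- 1
  }
  processed <- sweep(sweep(lg, 2, mu), 2, sd, `/`)
  list(processed = processed, transform = list(mu = mu, sd = sd))
}

#' Apply a stored preprocessing transform
#'
#' @param x raw-scale matrix (rows = states/time points) or vector.
#' @param transform the `transform` element returned by
#'   [preprocessStates()].
#' @return matrix (or vector) on the processed scale.
#' @export
applyTransform <- function(x, transform) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1, length(x))
  out <- sweep(sweep(log1p(x), 2, transform$mu), 2, transform$sd, `/`)
  if (vec) drop(out) else out
}

# Mclust resolves mclustBIC in its caller's frame, so the call must originate
# from a function whose environment is this namespace (not a tryCatch frame).
.fitGMM <- function(x, k) {
  mclust::Mclust(x, G = k, modelNames = "VVI", verbose = FALSE)
}

#' Cluster steady states into E and M phenotypes
#'
#' Evaluates the mean silhouette width (Euclidean distance on the processed
#' states) of Gaussian-mixture clusterings for k = 2..6 (k-means labels are
#' substituted at any k where the mixture fit degenerates), then fits a
#' 2-component diagonal-covariance Gaussian mixture for the final labels.
#' The cluster with the higher mean expression of the epithelial marker
#' (default Cdh1) is named "E", the other "M".
#'
#' @param processed processed state matrix (states in rows, gene columns).
#' @param eMarker epithelial marker gene used to name the clusters.
#' @param kRange integer vector of cluster counts to score.
#' @return list with `labels` (character "E"/"M" per state), `kSelected`,
#'   `silhouetteByK` (named numeric).
#' @importFrom mclust Mclust mclustBIC
#' @export
clusterStates <- function(processed, eMarker = "Cdh1", kRange = 2:6) {
  if (nrow(processed) < 2) stop("need at least 2 states to cluster")
  if (!eMarker %in% colnames(processed))
    stop("epithelial marker '", eMarker, "' not among genes")
  if (nrow(unique(processed)) < 2) stop("fewer than 2 distinct states")
  d <- stats::dist(processed)
  silByK <- stats::setNames(rep(NA_real_, length(kRange)), kRange)
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    if (k >= nrow(processed)) next
    fit <- tryCatch(.fitGMM(processed, k), error = function(e) NULL)
    cl <- if (!is.null(fit)) fit$classification
          else stats::kmeans(processed, centers = k, nstart = 10)$cluster
    if (length(unique(cl)) < 2) next
    silByK[ki] <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  }
  kSel <- if (all(is.na(silByK))) 2L
          else kRange[which.max(silByK)]
  fit2 <- tryCatch(.fitGMM(processed, 2), error = function(e) NULL)
  if (is.null(fit2))  # tiny or degenerate inputs: fall back to k-means
    cl <- stats::kmeans(processed, centers = 2, nstart = 10)$cluster
  else cl <- fit2$classification
  m1 <- mean(processed[cl == 1, eMarker])
  m2 <- mean(processed[cl == 2, eMarker])
  eCluster <- if (m1 >= m2) 1L else 2L
  labels <- ifelse(cl == eCluster, "E", "M")
  list(labels = labels, kSelected = kSel, silhouetteByK = silByK)
}

#' Simulate a randomized-parameter ensemble
#'
#' Draws `config$nModels` parameter sets, enumerates each model's steady
#' states, pools and preprocesses them, clusters the pooled states into E/M,
#' and returns everything as a [GRNStateEnsemble-class].
#'
#' @inheritParams sampleParameters
#' @param eMarker epithelial marker passed to [clusterStates()].
#' @return a [GRNStateEnsemble-class].
#' @export
simulateEnsemble <- function(topology, config = ensembleConfig(),
                             eMarker = "Cdh1") {
  nd <- geneNames(topology)
  paramsList <- vector("list", config$nModels)
  stateList <- vector("list", config$nModels)
  diverged <- 0L
  medianLevels <- estimateMedianLevels(topology, config)
  for (m in seq_len(config$nModels)) {
    p <- sampleParameters(topology, config, medianLevels)
    ss <- findSteadyStates(p, topology, config)
    paramsList[[m]] <- p
    stateList[[m]] <- ss$states
    diverged <- diverged + ss$nDiverged
  }
  nStates <- vapply(stateList, nrow, 0L)
  raw <- do.call(rbind, stateList[nStates > 0])
  modelId <- rep(seq_len(config$nModels), nStates)
  prep <- preprocessStates(raw)
  cl <- clusterStates(prep$processed, eMarker = eMarker)
  cd <- S4Vectors::DataFrame(
    model_id = modelId,
    state_id = unlist(lapply(nStates[nStates > 0], seq_len), use.names = FALSE),
    label = cl$labels)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = t(raw), processed = t(prep$processed)),
    colData = cd,
    metadata = list(params = paramsList, transform = prep$transform,
                    clustering = cl[c("kSelected", "silhouetteByK")],
                    config = config, topology = topology,
                    nDiverged = diverged))
  rownames(se) <- nd
  colnames(se) <- sprintf("m%d_s%d", cd$model_id, cd$state_id)
  methods::new("GRNStateEnsemble", se)
}

#' Extract E/M-bistable models from an ensemble
#'
#' Keeps models with exactly two unique steady states, one labelled E and one
#' M — the unit of all perturbation screens. By default models are further
#' required to be classifier-consistent: each steady state, fed unchanged to
#' the KNN classifier used for perturbation outcomes ([classifyState()]),
#' must recover its own cluster label. Without this filter a model whose
#' resting E state already classifies as M would count as "transitioned"
#' under a protocol that does nothing, biasing every efficacy estimate.
#'
#' @param ensemble a [GRNStateEnsemble-class].
#' @param selfConsistent require KNN self-consistency of both states.
#' @param k neighbour count used for the self-consistency check.
#' @return list of models; each a list with `model_id`, `params`, `states`
#'   (2 x genes raw matrix with rownames "E", "M").
#' @export
bistableModels <- function(ensemble, selfConsistent = TRUE, k = 25) {
  cd <- SummarizedExperiment::colData(ensemble)
  raw <- SummarizedExperiment::assay(ensemble, "raw")
  params <- modelParams(ensemble)
  kUse <- min(k, ncol(raw))
  out <- list()
  for (m in unique(cd$model_id)) {
    sel <- which(cd$model_id == m)
    if (length(sel) != 2) next
    lb <- cd$label[sel]
    if (!setequal(lb, c("E", "M"))) next
    st <- t(raw[, sel, drop = FALSE])
    rownames(st) <- lb
    st <- st[c("E", "M"), , drop = FALSE]
    if (selfConsistent &&
        !identical(unname(classifyState(st, ensemble, k = kUse)),
                   c("E", "M"))) next
    out[[length(out) + 1]] <- list(model_id = m, params = params[[m]],
                                   states = st)
  }
  out
}

#' Filter a list of clustered models for strict E/M bistability
#'
#' Generic list-level counterpart of [bistableModels()]: keeps entries whose
#' `labels` contain exactly one "E" and one "M" over exactly two states.
#'
#' @param models list; each element needs `states` (matrix) and `labels`.
#' @return the qualifying subset of `models`.
#' @export
selectBistable <- function(models) {
  Filter(function(m) {
    nrow(m$states) == 2 && setequal(m$labels, c("E", "M")) &&
      sum(m$labels == "E") == 1
  }, models)
}
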