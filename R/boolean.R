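#' Configuration for the Boolean spin engine
#'
#' Collects the knobs of the Metropolis clamp/quench protocol. One unit time
#' equals N single-node update attempts (random sequential update).
#'
#' @param T pseudo-temperature of the clamped phase (> 0; 0 allowed as the
#'   greedy limit).
#' @param tc clamp duration in unit times.
#' @param quenchT pseudo-temperature of the post-clamp quench phase.
#' @param quenchTime duration of the quench phase in unit times.
#' @param frustrationMax maximum frustration accepted for a starting state.
#' @param eScoreStartMin starting states must have epithelial score strictly
#'   greater than this.
#' @param mScoreEndMax a run succeeds when the final epithelial score is
#'   strictly less than this.
#' @param searchT pseudo-temperature used while searching for a
#'   low-frustration starting state; defaults to `T` (capped into (0, 4]).
#' @param maxAttempts cap on fresh random restarts of the starting-state
#'   search.
#' @param searchUnits unit times spent annealing per restart.
#' @param deltaESign sign convention of the pseudo-energy change; `+1` (the
#'   default) uses dE = +2 s_i sum_j J_ij s_j so that field-aligned spins are
#'   stable, `-1` the opposite convention, kept switchable for auditability.
#' @return a list of class `BooleanConfig`.
#' @export
booleanConfig <- function(T = 2, tc = 400, quenchT = 0.5, quenchTime = 10,
                          frustrationMax = 10, eScoreStartMin = 4,
                          mScoreEndMax = -4, searchT = NULL,
                          maxAttempts = 1000, searchUnits = 100,
                          deltaESign = 1L) {
  stopifnot(T >= 0, tc >= 0, quenchT >= 0, quenchTime >= 0,
            frustrationMax >= 0, maxAttempts >= 1, deltaESign %in% c(-1L, 1L))
  if (is.null(searchT)) searchT <- min(max(T, 0.5), 4)
  structure(list(T = T, tc = tc, quenchT = quenchT, quenchTime = quenchTime,
                 frustrationMax = frustrationMax,
                 eScoreStartMin = eScoreStartMin, mScoreEndMax = mScoreEndMax,
                 searchT = searchT, maxAttempts = maxAttempts,
                 searchUnits = searchUnits,
                 deltaESign = as.integer(deltaESign)),
            class = "BooleanConfig")
}

.asSpin <- function(state) {
  s <- as.integer(state)
  if (!all(s %in% c(-1L, 1L))) stop("spin state entries must be +1 or -1")
  s
}

# Resolve a clamp specification (named vector of +/-1, names = genes) against
# the gene order of J. Returns list(mask, values).
.clampMask <- function(clamp, genes) {
  mask <- rep(FALSE, length(genes))
  vals <- integer(0)
  idx <- integer(0)
  if (length(clamp)) {
    if (is.null(names(clamp))) stop("clamp must be a named vector")
    idx <- match(names(clamp), genes)
    if (anyNA(idx)) stop("clamp gene not in topology: ",
                         paste(names(clamp)[is.na(idx)], collapse = ", "))
    vals <- .asSpin(clamp)
    mask[idx] <- TRUE
  }
  list(mask = mask, idx = idx, values = vals)
}

#' Frustration of a spin state
#'
#' Counts the directed regulatory links violated by a binary state: a link
#' j -> i with sign J\[i, j\] is unsatisfied when `s_i * J[i, j] * s_j < 0`.
#' Each directed link is counted once. The count is invariant under a global
#' spin flip.
#'
#' @param state spin vector with entries +1/-1, in topology node order.
#' @param J signed interaction matrix from [interactionMatrix()].
#' @return non-negative integer.
#' @export
frustration <- function(state, J) {
  s <- .asSpin(state)
  if (length(s) != nrow(J)) stop("dimension mismatch between state and J")
  cpp_frustration(J, s)
}

#' Epithelial score of a spin state
#'
#' The signed sum `sum_i score_i * s_i` over the annotation; with the default
#' EMT annotation (three +1 and three -1 markers) it ranges over \[-6, +6\].
#'
#' @param state spin vector (+1/-1) in node order.
#' @param annotation named integer score vector covering the nodes, in the
#'   same order as `state`.
#' @return integer score.
#' @export
epithelialScore <- function(state, annotation) {
  s <- .asSpin(state)
  if (length(s) != length(annotation))
    stop("annotation length does not match state length")
  sum(as.integer(annotation) * s)
}

#' One Metropolis update attempt
#'
#' Chooses one node uniformly at random; if it is clamped nothing happens,
#' otherwise the pseudo-energy change of flipping it is computed and the flip
#' accepted with probability `min(1, exp(-dE / T))`. At most one spin differs
#' between input and output.
#'
#' @inheritParams frustration
#' @param T pseudo-temperature (>= 0; at 0 flips are accepted iff dE <= 0).
#' @param clamp named vector of +/-1 clamp values (may be empty).
#' @param deltaESign pseudo-energy sign convention, see [booleanConfig()].
#' @return updated spin vector.
#' @export
metropolisStep <- function(state, J, T, clamp = integer(0), deltaESign = 1L) {
  s <- .asSpin(state)
  cl <- .clampMask(clamp, rownames(J) %||% as.character(seq_len(nrow(J))))
  s[cl$idx] <- cl$values
  res <- cpp_metropolis_run(J, s, T, 1, cl$mask, as.integer(deltaESign), FALSE)
  res$state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find a low-frustration epithelial starting state
#'
#' Draws a fresh random spin configuration and anneals it at
#' `config$searchT` until the frustration drops to `config$frustrationMax` or
#' below; the resulting state is accepted if its epithelial score exceeds
#' `config$eScoreStartMin`, otherwise a new random restart is made, up to
#' `config$maxAttempts` restarts.
#'
#' @param J signed interaction matrix.
#' @param annotation named score vector in node order.
#' @param config a [booleanConfig()].
#' @return spin vector satisfying both acceptance conditions.
#' @export
findInitialState <- function(J, annotation, config = booleanConfig()) {
  bestF <- Inf
  for (a in seq_len(config$maxAttempts)) {
    res <- cpp_low_frustration_search(J, config$searchT, config$frustrationMax,
                                      config$searchUnits, config$deltaESign)
    bestF <- min(bestF, res$frustration)
    if (res$found &&
        epithelialScore(res$state, annotation) > config$eScoreStartMin)
      return(res$state)
  }
  stop(sprintf(paste0("no starting state with frustration <= %d and ",
                      "epithelial score > %d found in %d attempts ",
                      "(best frustration seen: %d)"),
               config$frustrationMax, config$eScoreStartMin,
               config$maxAttempts, bestF))
}

#' Run the clamp/quench transition protocol
#'
#' Clamps the given nodes to their clamp values, runs `tc` unit times of
#' Metropolis dynamics at temperature `config$T`, removes the clamp, quenches
#' for `config$quenchTime` unit times at `config$quenchT`, and calls the run
#' successful when the final epithelial score is below `config$mScoreEndMax`.
#'
#' @param state0 starting spin vector (typically an epithelial state from
#'   [findInitialState()]).
#' @inheritParams findInitialState
#' @param clamp named vector of +/-1 values to hold fixed during the clamped
#'   phase.
#' @param trace if `TRUE`, the accepted flips of the clamped phase are
#'   returned as a data.frame (attempt, node, new spin).
#' @return list with elements `success`, `final`, `score`, and optionally
#'   `trace`.
#' @export
runClampProtocol <- function(state0, J, annotation, clamp,
                             config = booleanConfig(), trace = FALSE) {
  N <- nrow(J)
  s <- .asSpin(state0)
  genes <- rownames(J) %||% names(annotation) %||% as.character(seq_len(N))
  cl <- .clampMask(clamp, genes)
  s[cl$idx] <- cl$values
  res <- cpp_metropolis_run(J, s, config$T, config$tc * N, cl$mask,
                            config$deltaESign, trace)
  s <- res$state
  flips <- if (trace) res$flips else NULL
  if (trace && !is.null(flips) && length(cl$idx))
    flips$gene <- genes[flips$node]
  noClamp <- rep(FALSE, N)
  s <- cpp_metropolis_run(J, s, config$quenchT, config$quenchTime * N,
                          noClamp, config$deltaESign, FALSE)$state
  sc <- epithelialScore(s, annotation)
  out <- list(success = sc < config$mScoreEndMax, final = s, score = sc)
  if (trace) out$trace <- flips
  out
}

# Enumerate the clamp-value combinations to try for a node set: scored nodes
# are clamped in the mesenchymal direction (+1-scored off, -1-scored on);
# score-0 nodes contribute both alternatives.
.clampCandidates <- function(nodes, annotation) {
  per <- lapply(nodes, function(g) {
    sc <- annotation[[g]]
    if (sc > 0) -1L else if (sc < 0) 1L else c(-1L, 1L)
  })
  grid <- expand.grid(per, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r)
    stats::setNames(as.integer(grid[r, ]), nodes))
}

#' Screen clamp signals in the Boolean model
#'
#' For each node set, runs `nRuns` independent clamp/quench protocols, each
#' from a freshly found epithelial starting state, clamping scored nodes in
#' their mesenchymal direction. For score-0 nodes both clamp values are
#' tried and the better success percentage is reported.
#'
#' @inheritParams findInitialState
#' @param topology a [GRNTopology-class] (supplies gene order and `J`).
#' @param nodeSets list of character vectors (1 or 2 genes each; larger sets
#'   are accepted by the engine).
#' @param nRuns runs per clamp-value combination.
#' @return data.frame with columns `node_set`, `clamp_values`, `n_runs`,
#'   `success_percent`.
#' @export
screenClamps <- function(topology, annotation, nodeSets,
                         config = booleanConfig(), nRuns = 100) {
  if (length(nodeSets) == 0) stop("nodeSets must be non-empty")
  J <- interactionMatrix(topology)
  ann <- annotation[geneNames(topology)]
  rows <- lapply(nodeSets, function(ns) {
    cands <- .clampCandidates(ns, ann)
    best <- NULL
    for (cv in cands) {
      succ <- 0L
      for (r in seq_len(nRuns)) {
        s0 <- findInitialState(J, ann, config)
        if (runClampProtocol(s0, J, ann, cv, config)$success)
          succ <- succ + 1L
      }
      pct <- 100 * succ / nRuns
      if (is.null(best) || pct > best$pct) best <- list(cv = cv, pct = pct)
    }
    data.frame(node_set = paste(ns, collapse = "+"),
               clamp_values = paste(sprintf("%s=%+d", names(best$cv), best$cv),
                                    collapse = ","),
               n_runs = nRuns, success_percent = best$pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
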