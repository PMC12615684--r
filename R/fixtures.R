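#' Toggle-switch fixture
#'
#' The canonical bistable motif standing in for the E/M dichotomy: two
#' mutually inhibiting, self-activating genes A and B, annotated A = +1
#' (epithelial-like) and B = -1 (mesenchymal-like). Its Boolean fixed points
#' at zero temperature are exactly (+1, -1) and (-1, +1).
#'
#' @return list with `topology` ([GRNTopology-class]) and `annotation`
#'   (named integer vector).
#' @export
makeToggleSwitch <- function() {
  ed <- data.frame(source = c("A", "B", "A", "B"),
                   target = c("B", "A", "A", "B"),
                   sign = c(-1L, -1L, 1L, 1L))
  list(topology = GRNTopology(nodes = c("A", "B"), edges = ed),
       annotation = c(A = 1L, B = -1L))
}

#' Random signed GRN fixture
#'
#' Samples `nEdges` distinct directed edges (no self-loops) uniformly among
#' the ordered node pairs; each edge is activating with probability
#' `activationFraction`. Deterministic given `seed`.
#'
#' @param nNodes number of genes (named g1..gN).
#' @param nEdges number of edges; must not exceed `nNodes * (nNodes - 1)`.
#' @param activationFraction probability in \[0, 1\] that an edge activates.
#' @param seed integer RNG seed.
#' @return a [GRNTopology-class].
#' @export
makeRandomGRN <- function(nNodes, nEdges, activationFraction = 0.5, seed = 1) {
  if (nEdges > nNodes * (nNodes - 1))
    stop("nEdges exceeds the ", nNodes * (nNodes - 1),
         " possible distinct directed edges")
  if (activationFraction < 0 || activationFraction > 1)
    stop("activationFraction must be in [0, 1]")
  nd <- paste0("g", seq_len(nNodes))
  pairs <- expand.grid(source = seq_len(nNodes), target = seq_len(nNodes))
  pairs <- pairs[pairs$source != pairs$target, ]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sel <- pairs[sample(nrow(pairs), nEdges), ]
  sgn <- ifelse(stats::runif(nEdges) < activationFraction, 1L, -1L)
  GRNTopology(nodes = nd,
              edges = data.frame(source = nd[sel$source],
                                 target = nd[sel$target], sign = sgn))
}

#' Build an annotation from marker lists
#'
#' @param topology a [GRNTopology-class].
#' @param eGenes genes scored +1 (epithelial markers).
#' @param mGenes genes scored -1 (mesenchymal markers); must be disjoint
#'   from `eGenes`.
#' @return named integer vector covering every node (0 for unscored genes).
#' @export
makeAnnotation <- function(topology, eGenes = character(0),
                           mGenes = character(0)) {
  if (length(intersect(eGenes, mGenes)))
    stop("eGenes and mGenes overlap: ",
         paste(intersect(eGenes, mGenes), collapse = ", "))
  nd <- geneNames(topology)
  unknown <- setdiff(c(eGenes, mGenes), nd)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  ann <- stats::setNames(integer(length(nd)), nd)
  ann[eGenes] <- 1L
  ann[mGenes] <- -1L
  ann
}

#' Synthetic 26-node EMT-like network
#'
#' A SYNTHETIC stand-in for published 26-node/100-edge EMT transcriptional
#' networks, built once from their commonly reported structural features: two
#' mutually inhibiting teams (epithelial microRNAs/factors vs mesenchymal
#' transcription factors), with Zeb1 the highest out-degree node (11 outgoing
#' edges including a self-activation) and Snai1 next (10 outgoing edges
#' including a self-inhibition). It is NOT the published network: edge-level
#' results (e.g. exact centrality scores or per-gene efficacies) are not
#' comparable to values reported for the real graph. To analyze the published
#' network, obtain its `.topo` file and score table from the original
#' authors' repository and load them with [readTopo()]/[readAnnotation()].
#'
#' The default annotation scores Cdh1, miR200b and miR34a as +1 and Zeb1,
#' Snai1 and Vim as -1, so the maximum epithelial score is +6.
#'
#' @return list with `topology` (26 nodes, 100 edges) and `annotation`.
#' @export
syntheticEmtNetwork <- function() {
  eTeam <- c("Cdh1", "miR200a", "miR200b", "miR200c", "miR141", "miR34a",
             "miR101", "miR205", "miR30c", "Ovol2", "Grhl2")
  mTeam <- c("Zeb1", "Zeb2", "Snai1", "Snai2", "Twist1", "Twist2", "Foxc2",
             "Vim", "Tgfb", "Gsc", "Klf8", "Tcf3", "Fn1", "Sparc", "Mmp9")
  nodes <- c(eTeam, mTeam)
  E <- function(s, t, sg) data.frame(source = s, target = t, sign = sg)
  core <- rbind(
    # Zeb1: out-degree 11, self-activating hub of the mesenchymal team
    E("Zeb1", "Zeb1", 1L),
    E("Zeb1", c("Cdh1", "miR200a", "miR200b", "miR200c", "miR141", "miR34a",
                "miR101"), rep(-1L, 7)),
    E("Zeb1", c("Vim", "Fn1", "Foxc2"), rep(1L, 3)),
    # Snai1: out-degree 10, self-inhibiting
    E("Snai1", c("Snai1", "Cdh1", "miR200b", "miR34a", "miR141"), rep(-1L, 5)),
    E("Snai1", c("Zeb1", "Zeb2", "Twist1", "Vim", "Klf8"), rep(1L, 5)),
    # canonical microRNA / TF double-negative feedback
    E(c("miR200a", "miR200b", "miR200c"), "Zeb1", rep(-1L, 3)),
    E(c("miR200a", "miR200b", "miR200c"), "Zeb2", rep(-1L, 3)),
    E("miR34a", c("Snai1", "Snai2"), rep(-1L, 2)),
    E("miR141", "Zeb2", -1L),
    E("miR101", "Zeb1", -1L),
    E("miR205", "Zeb2", -1L),
    E("miR30c", "Snai1", -1L),
    # epithelial maintenance
    E("Grhl2", c("Cdh1", "miR200b"), rep(1L, 2)),
    E("Ovol2", c("Cdh1", "miR34a"), rep(1L, 2)),
    E("Grhl2", "Zeb1", -1L),
    E("Ovol2", "Zeb1", -1L),
    E("Cdh1", c("miR200a", "miR34a"), rep(1L, 2)),
    # mesenchymal cascade
    E("Tgfb", c("Snai1", "Zeb2", "Twist1"), rep(1L, 3)),
    E("Tgfb", "miR200c", -1L),
    E("Snai2", c("Cdh1", "miR200a"), rep(-1L, 2)),
    E("Snai2", "Zeb1", 1L),
    E("Zeb2", c("Cdh1", "miR200c"), rep(-1L, 2)),
    E("Zeb2", "Vim", 1L),
    E("Twist1", c("Snai2", "Zeb2", "Fn1"), rep(1L, 3)),
    E("Twist1", "Cdh1", -1L),
    E("Twist2", c("Snai2", "Vim"), rep(1L, 2)),
    E("Twist2", "Cdh1", -1L),
    E("Foxc2", c("Vim", "Mmp9"), rep(1L, 2)),
    E("Klf8", "Cdh1", -1L),
    E("Tcf3", "Cdh1", -1L),
    E("Gsc", "Snai1", 1L))
  key <- function(d) paste(d$source, d$target, sep = "\r")
  stopifnot(!anyDuplicated(key(core)))
  # Deterministic round-robin fill to exactly 100 edges with team-consistent
  # links (cross-team inhibition, within-team activation). Zeb1 and Snai1 are
  # excluded as fill sources and other sources are capped at out-degree 8,
  # keeping Zeb1 (11) and Snai1 (10) the two largest hubs.
  fillSources <- setdiff(nodes, c("Zeb1", "Snai1"))
  candOf <- lapply(fillSources, function(s) {
    sTeamE <- s %in% eTeam
    tgts <- setdiff(nodes, s)
    data.frame(source = s, target = tgts,
               sign = ifelse((tgts %in% eTeam) == sTeamE, 1L, -1L))
  })
  names(candOf) <- fillSources
  edges <- core
  ptr <- stats::setNames(rep(1L, length(fillSources)), fillSources)
  repeat {
    added <- FALSE
    for (s in fillSources) {
      if (nrow(edges) >= 100) break
      if (sum(edges$source == s) >= 8) next
      cands <- candOf[[s]]
      while (ptr[s] <= nrow(cands) &&
             key(cands[ptr[s], ]) %in% key(edges))
        ptr[s] <- ptr[s] + 1L
      if (ptr[s] <= nrow(cands)) {
        edges <- rbind(edges, cands[ptr[s], ])
        ptr[s] <- ptr[s] + 1L
        added <- TRUE
      }
    }
    if (nrow(edges) >= 100 || !added) break
  }
  stopifnot(nrow(edges) == 100)
  rownames(edges) <- NULL
  tp <- GRNTopology(nodes = nodes, edges = edges)
  list(topology = tp,
       annotation = makeAnnotation(tp, eGenes = c("Cdh1", "miR200b", "miR34a"),
                                   mGenes = c("Zeb1", "Snai1", "Vim")))
}
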