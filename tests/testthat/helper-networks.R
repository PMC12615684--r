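# Shared fixtures built in code. Everything is seeded by the calling test.

# 3-node chain A -> B -> C (activations)
chainTopology <- function() {
  GRNTopology(edges = data.frame(source = c("A", "B"),
                                 target = c("B", "C"),
                                 sign = c(1L, 1L)))
}

# Write a topology to a temp .topo file and return the path
tempTopo <- function(topology) {
  f <- tempfile(fileext = ".topo")
  writeTopo(topology, f)
  f
}

# Boolean config scaled to the toggle switch (max |score| = 2)
toggleBooleanConfig <- function(...) {
  booleanConfig(eScoreStartMin = 1, mScoreEndMax = -1, ...)
}

# Small, quick ensemble settings for tests
quickEnsembleConfig <- function(nModels = 40, nICs = 20, ...) {
  ensembleConfig(nModels = nModels, nICs = nICs, ...)
}

# The bistable model of an ensemble whose E and M states are farthest apart
# (log1p scale) -- avoids near-degenerate pairs in dynamical tests.
mostSeparatedModel <- function(bm) {
  sep <- vapply(bm, function(m)
    sum((log1p(m$states["E", ]) - log1p(m$states["M", ]))^2), numeric(1))
  bm[[which.max(sep)]]
}

# Strongly bistable hand-chosen toggle-switch parameter set. Production
# rates are slightly asymmetric so that the symmetric diagonal (an invariant
# manifold of the perfectly symmetric system) is not an attractor.
toggleParams <- function(G = c(A = 55, B = 45), k = c(A = 0.5, B = 0.5),
                         lamInh = 0.02, lamAct = 10, thr = 100, hill = 4L) {
  ed <- edgeTable(makeToggleSwitch()$topology)
  act <- ed$sign > 0
  ed$lambda <- ifelse(act, lamAct, lamInh)
  ed$threshold <- thr
  ed$hill <- hill
  structure(list(G = G, k = k, edges = ed), class = "RacipeParams")
}

# Independent brute-force group betweenness via igraph::all_shortest_paths
igraphGroupBetweenness <- function(topology, group) {
  g <- igraph::graph_from_data_frame(
    edgeTable(topology)[, c("source", "target")],
    directed = TRUE, vertices = geneNames(topology))
  nd <- geneNames(topology)
  others <- setdiff(nd, group)
  total <- 0
  for (s in others) for (t in others) {
    if (s == t) next
    asp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = s, to = t, mode = "out"))$res
    if (!length(asp)) next
    through <- vapply(asp, function(p)
      any(names(p) %in% group), logical(1))
    total <- total + mean(through)
  }
  total
}
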