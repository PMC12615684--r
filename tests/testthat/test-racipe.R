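test_that("parameter sampling has the documented shapes, ranges and counts", {
  set.seed(8)
  emt <- syntheticEmtNetwork()
  cfg <- ensembleConfig()
  p <- sampleParameters(emt$topology, cfg)
  expect_length(p$G, 26)
  expect_length(p$k, 26)
  expect_equal(nrow(p$edges), 100)          # 2N + 3E = 352 parameters total
  expect_true(all(p$G >= 1 & p$G <= 100))
  expect_true(all(p$k >= 0.1 & p$k <= 1))
  expect_true(all(p$edges$hill %in% 1:6))
  act <- p$edges$sign > 0
  expect_true(all(p$edges$lambda[act] >= 1 & p$edges$lambda[act] <= 100))
  expect_true(all(p$edges$lambda[!act] >= 0.01 & p$edges$lambda[!act] <= 1))
  expect_true(all(p$edges$threshold > 0))

  # no-edge topology: gene parameters only
  lone <- GRNTopology(nodes = c("X", "Y"))
  p0 <- sampleParameters(lone, cfg)
  expect_equal(nrow(p0$edges), 0L)

  # reproducibility under a fixed seed
  set.seed(123); p1 <- sampleParameters(emt$topology, cfg)
  set.seed(123); p2 <- sampleParameters(emt$topology, cfg)
  expect_identical(p1, p2)
})

test_that("the ODE right-hand side follows the shifted-Hill algebra", {
  # unregulated gene: dA/dt = G - kA, steady state G/k
  lone <- GRNTopology(nodes = "X")
  p <- structure(list(G = c(X = 10), k = c(X = 0.5),
                      edges = data.frame(source = character(),
                                         target = character(),
                                         sign = integer(), lambda = numeric(),
                                         threshold = numeric(),
                                         hill = integer())),
                 class = "RacipeParams")
  expect_equal(racipeRHS(c(X = 20), p, lone), c(X = 0))
  expect_equal(racipeRHS(c(X = 0), p, lone), c(X = 10))

  # one activator B -> A, lambda = 4, G_A = 40, k_A = 1:
  # production 10 at B = 0, 40 at saturation, 25 at B = B0
  tp <- GRNTopology(nodes = c("B", "A"),
                    edges = data.frame(source = "B", target = "A", sign = 1L))
  pa <- structure(list(G = c(B = 1, A = 40), k = c(B = 1, A = 1),
                       edges = data.frame(source = "B", target = "A",
                                          sign = 1L, lambda = 4,
                                          threshold = 10, hill = 2L)),
                  class = "RacipeParams")
  prodAt <- function(B) racipeRHS(c(B = B, A = 0), pa, tp)[["A"]]
  expect_equal(prodAt(0), 10)
  expect_equal(prodAt(1e9), 40, tolerance = 1e-6)
  expect_equal(prodAt(10), 25)

  # one inhibitor with lambda = 0.25: max/min production ratio = 4, and the
  # shifted-Hill factor is bounded and monotone in the regulator level
  pi <- structure(list(G = c(B = 1, A = 40), k = c(B = 1, A = 1),
                       edges = data.frame(source = "B", target = "A",
                                          sign = -1L, lambda = 0.25,
                                          threshold = 10, hill = 3L)),
                  class = "RacipeParams")
  prodI <- function(B) racipeRHS(c(B = B, A = 0), pi, tp)[["A"]]
  expect_equal(prodI(0) / prodI(1e9), 4, tolerance = 1e-6)
  lv <- vapply(c(0, 1, 5, 10, 50, 1e4), prodI, numeric(1))
  expect_true(all(diff(lv) < 0))
  expect_true(all(lv >= prodI(1e9) - 1e-9 & lv <= prodI(0) + 1e-9))

  expect_error(racipeRHS(c(B = -1, A = 0), pi, tp), "non-negative")
})

test_that("steady-state enumeration finds the analytic and bistable states", {
  # unregulated 2-gene system converges to (G1/k1, G2/k2) from any start
  lone <- GRNTopology(nodes = c("X", "Y"))
  set.seed(14)
  p <- sampleParameters(lone, ensembleConfig())
  ss <- findSteadyStates(p, lone, ensembleConfig(nICs = 30))
  expect_equal(nrow(ss$states), 1L)
  expect_equal(unname(ss$states[1, ]), unname(p$G / p$k), tolerance = 1e-4)

  # hand-parameterized toggle switch: two asymmetric states, each matching
  # a dense-grid oracle
  ts <- makeToggleSwitch()
  pT <- toggleParams()
  set.seed(15)
  ss2 <- findSteadyStates(pT, ts$topology, ensembleConfig(nICs = 60))
  expect_equal(nrow(ss2$states), 2L)
  hiA <- ss2$states[which.max(ss2$states[, "A"]), ]
  expect_gt(hiA[["A"]], hiA[["B"]])
  # every returned state satisfies the residual tolerance through the rhs
  for (r in seq_len(nrow(ss2$states)))
    expect_lt(max(abs(racipeRHS(ss2$states[r, ], pT, ts$topology))), 1e-6)
  # dense grid of deterministic initial conditions finds the same two states
  grid <- as.matrix(expand.grid(A = c(0.1, 1, 10, 60, 100),
                                B = c(0.1, 1, 10, 60, 100)))
  res <- cpp_find_states(grid, pT$G, pT$k,
                         match(pT$edges$source, c("A", "B")) - 1L,
                         match(pT$edges$target, c("A", "B")) - 1L,
                         pT$edges$lambda, pT$edges$threshold, pT$edges$hill,
                         0.1, 200, 1e-6, 10L)
  uniq <- unique(round(log1p(res$states[res$converged, ]), 2))
  expect_equal(nrow(uniq), 2L)
  expect_equal(sort(uniq[, 1]), sort(round(log1p(ss2$states[, "A"]), 2)))
})

test_that("more initial conditions never lose states (matched seeds)", {
  ts <- makeToggleSwitch()
  pT <- toggleParams()
  for (seed in c(5, 6)) {
    set.seed(seed)
    n1 <- nrow(findSteadyStates(pT, ts$topology,
                                ensembleConfig(nICs = 10))$states)
    set.seed(seed)
    n2 <- nrow(findSteadyStates(pT, ts$topology,
                                ensembleConfig(nICs = 20))$states)
    expect_gte(n2, n1)
  }
})

test_that("preprocessing anchors zero, handles constants and standardizes", {
  m <- cbind(a = c(0, exp(1) - 1, 0, exp(1) - 1),
             b = c(1, 1, 1, 1),
             c = c(0, 1, 2, 3))
  expect_warning(pp <- preprocessStates(m), "zero-variance")
  expect_equal(unname(pp$processed[1, "a"]), unname(-pp$processed[2, "a"]))
  expect_true(all(pp$processed[, "b"] == 0))
  expect_equal(colMeans(pp$processed[, c("a", "c")]), c(a = 0, c = 0))
  expect_equal(apply(pp$processed[, c("a", "c")], 2, stats::sd),
               c(a = 1, c = 1))
  # log1p anchors x = 0 at 0 before standardization
  expect_equal(log1p(0), 0)
  # column (0, e-1) has log1p values (0, 1): with the sample-sd denominator
  # (sd = 1/sqrt(2)) the standardized column is (-1, +1)/sqrt(2)
  two <- cbind(g = c(0, exp(1) - 1))
  pp2 <- preprocessStates(two)
  expect_equal(unname(pp2$processed[, "g"]), c(-1, 1) / sqrt(2))

  # stored transform reproduces the processed values on reuse
  expect_equal(applyTransform(m, pp$transform), unname(pp$processed),
               ignore_attr = TRUE)
})

test_that("clustering selects k = 2 on separated blobs and names E by marker", {
  set.seed(44)
  blob1 <- matrix(stats::rnorm(40 * 3, mean = 0, sd = 0.2), 40)
  blob2 <- matrix(stats::rnorm(40 * 3, mean = 3, sd = 0.2), 40)
  x <- rbind(blob1, blob2)
  colnames(x) <- c("Cdh1", "g2", "g3")
  cl <- clusterStates(x)
  expect_equal(cl$kSelected, 2L)
  expect_equal(which.max(cl$silhouetteByK), 1L, ignore_attr = TRUE)
  # the higher-Cdh1 blob is E regardless of component indexing
  expect_true(all(cl$labels[41:80] == "E"))
  expect_true(all(cl$labels[1:40] == "M"))

  # label assignment invariant under row permutation
  set.seed(45)
  perm <- sample(nrow(x))
  cl2 <- clusterStates(x[perm, ])
  expect_equal(cl2$labels, cl$labels[perm])

  expect_error(clusterStates(x[1, , drop = FALSE]), "at least 2")
  same <- x[c(1, 1, 1), ]
  expect_error(clusterStates(same), "distinct")
})

test_that("bistable selection keeps exactly one E and one M state", {
  mk <- function(labels) {
    list(states = matrix(seq_len(2 * length(labels)), length(labels)),
         labels = labels)
  }
  models <- list(mk("E"), mk(c("E", "M")), mk(c("E", "E")),
                 mk(c("E", "M", "M")))
  kept <- selectBistable(models)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$labels, c("E", "M"))
})

test_that("ensemble simulation yields clustered, mostly multistable models", {
  set.seed(70)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology, quickEnsembleConfig(), eMarker = "A")
  expect_s4_class(ens, "GRNStateEnsemble")
  cd <- SummarizedExperiment::colData(ens)
  expect_true(all(stateLabels(ens) %in% c("E", "M")))
  # every stored state satisfies the residual tolerance through the rhs
  raw <- t(SummarizedExperiment::assay(ens, "raw"))
  params <- modelParams(ens)
  for (i in sample(nrow(raw), 10)) {
    m <- cd$model_id[i]
    expect_lt(max(abs(racipeRHS(raw[i, ], params[[m]], ts$topology))), 1e-6)
    expect_true(all(raw[i, ] >= 0))
  }
  bm <- bistableModels(ens)
  expect_gt(length(bm), 0)
  for (m in bm) expect_equal(rownames(m$states), c("E", "M"))
})
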