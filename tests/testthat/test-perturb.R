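test_that("signal enumeration covers singletons plus unordered pairs", {
  emt <- syntheticEmtNetwork()
  expect_length(enumerateSignals(emt$topology), 351L)
  ts <- makeToggleSwitch()
  expect_length(enumerateSignals(ts$topology), 3L)
  tp5 <- makeRandomGRN(5, 5, seed = 1)
  sigs <- enumerateSignals(tp5)
  expect_length(sigs, 15L)
  # stable ordering: singletons first, then combn pairs
  expect_equal(sigs[[1]], "g1")
  expect_equal(sigs[[6]], c("g1", "g2"))
  keys <- vapply(sigs, paste, "", collapse = "+")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("the OU update has the exact discrete-time moments", {
  # deterministic parts
  expect_equal(ouStep(2, h = 1, tau = 10, Dg = 0, z = 0.7), 2 * exp(-0.1))
  expect_equal(ouStep(5, h = 1e6, tau = 10, Dg = 3, z = 1.2), 3 * 1.2,
               tolerance = 1e-9)

  # stationary sd and lag-h autocorrelation from a long iterated path
  set.seed(55)
  h <- 0.5; tau <- 10; Dg <- 2
  n <- 2e5
  u <- numeric(n)
  for (i in 2:n) u[i] <- ouStep(u[i - 1], h, tau, Dg)
  emp <- stats::sd(u[1000:n])
  expect_lt(abs(emp - Dg) / Dg, 0.02)
  ac <- stats::cor(u[1000:(n - 1)], u[1001:n])
  se <- (1 - exp(-2 * h / tau)) / sqrt(n - 1000) # rough 1-sigma scale
  expect_lt(abs(ac - exp(-h / tau)), 3 * max(se, 0.003))
})

test_that("KNN classification is exact at references and breaks ties toward M", {
  set.seed(66)
  refE <- matrix(stats::rnorm(30 * 2, mean = 0, sd = 0.1), 30)
  refM <- matrix(stats::rnorm(30 * 2, mean = 2, sd = 0.1), 30)
  proc <- rbind(refE, refM)
  colnames(proc) <- c("gA", "gB")
  # identity transform so raw == processed coordinates
  idTrans <- list(mu = c(gA = 0, gB = 0), sd = c(gA = 1, gB = 1))
  ref <- list(processed = proc, labels = rep(c("E", "M"), each = 30),
              transform = idTrans)
  raw <- expm1(proc) # classifyState applies log1p internally
  for (i in c(1, 31)) {
    expect_equal(classifyState(raw[i, ], ref, k = 1), ref$labels[i])
  }
  # k = 1 on separated blobs follows the nearest blob
  expect_equal(classifyState(expm1(c(-0.1, 0.1)), ref, k = 1), "E")
  expect_equal(classifyState(expm1(c(2.1, 2.0)), ref, k = 1), "M")

  # constructed exact tie with even k: majority split 1-1 resolves to M
  tie <- list(processed = rbind(c(-1, 0), c(1, 0)), labels = c("E", "M"),
              transform = list(mu = c(0, 0), sd = c(1, 1)))
  colnames(tie$processed) <- c("gA", "gB")
  expect_equal(classifyState(expm1(c(0, 0)), tie, k = 2), "M")

  expect_error(classifyState(raw[1, ], ref, k = 100), "exceeds")
})

test_that("perturbation runs honour trivial protocols and clamp contracts", {
  set.seed(91)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology, quickEnsembleConfig(), eMarker = "A")
  bm <- bistableModels(ens)
  expect_gt(length(bm), 0)
  m <- bm[[1]]

  # identity protocol: no time, no noise
  pr0 <- runPerturbation(m, ts$topology, character(0), ens, D = 0,
                         protocol = protocolConfig(tSignal = 0, tRelax = 0))
  expect_false(pr0$transitioned)
  expect_equal(unname(pr0$final), unname(m$states["E", ]))

  # clamping every gene at its target value forces the transition
  prAll <- runPerturbation(m, ts$topology, c("A", "B"), ens, D = 0,
                           protocol = protocolConfig(tSignal = 50,
                                                     tRelax = 50))
  expect_true(prAll$transitioned)

  # clamped gene is bit-identical to its target at every sampled time of
  # the signal phase
  prT <- runPerturbation(m, ts$topology, "B", ens, D = 0.1,
                         protocol = protocolConfig(tSignal = 20, tRelax = 10,
                                                   recordEvery = 1))
  sig <- prT$time <= 20
  expect_true(all(prT$trajectory[sig, "B"] == m$states["M", "B"]))

  # D = 0 with no signal keeps the model at its steady state
  prS <- runPerturbation(m, ts$topology, character(0), ens, D = 0,
                         protocol = protocolConfig(tSignal = 100, tRelax = 0))
  expect_lt(max(abs(prS$final - m$states["E", ])), 1e-3)
})

test_that("deterministic efficacy is trial-invariant and bounded", {
  set.seed(92)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology, quickEnsembleConfig(), eMarker = "A")
  bm <- bistableModels(ens)
  p1 <- protocolConfig(tSignal = 100, tRelax = 50, nTrials = 1)
  p3 <- protocolConfig(tSignal = 100, tRelax = 50, nTrials = 3)
  e1 <- signalEfficacy(bm, ts$topology, "B", ens, D = 0, protocol = p1)
  e3 <- signalEfficacy(bm, ts$topology, "B", ens, D = 0, protocol = p3)
  expect_equal(e1, e3)
  expect_gte(e1, 0); expect_lte(e1, 100)
  expect_error(signalEfficacy(list(), ts$topology, "B", ens), "empty")
})

test_that("noise-free controls never transition spontaneously", {
  set.seed(93)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology, quickEnsembleConfig(), eMarker = "A")
  bm <- bistableModels(ens)
  sp <- spontaneousRates(bm, ts$topology, 0,
                         ens, protocol = protocolConfig(tSignal = 100,
                                                        tRelax = 20))
  expect_equal(sp$emt_percent, 0)
  expect_equal(sp$met_percent, 0)
})

test_that("strong noise drives switching in both directions on the toggle", {
  set.seed(94)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology,
                          quickEnsembleConfig(nModels = 60), eMarker = "A")
  bm <- bistableModels(ens)
  expect_gte(length(bm), 3)
  sp <- spontaneousRates(bm, ts$topology, 0.5, ens,
                         protocol = protocolConfig(tSignal = 200, tRelax = 30))
  expect_gt(sp$emt_percent + sp$met_percent, 0)
})

test_that("transition times are detected from sampled trajectories", {
  set.seed(95)
  ts <- makeToggleSwitch()
  ens <- simulateEnsemble(ts$topology, quickEnsembleConfig(), eMarker = "A")
  bm <- bistableModels(ens)
  m <- bm[[1]]
  k <- min(10L, ncol(SummarizedExperiment::assay(ens)))

  # trajectory that starts in M reports time 0
  prM <- runPerturbation(m, ts$topology, character(0), ens, D = 0,
                         startLabel = "M", targetLabel = "E",
                         protocol = protocolConfig(tSignal = 5, tRelax = 0,
                                                   recordEvery = 1))
  expect_equal(transitionTime(prM, ens, targetLabel = "M", k = k), 0)

  # non-transitioning trajectory has no arrival time
  prE <- runPerturbation(m, ts$topology, character(0), ens, D = 0,
                         protocol = protocolConfig(tSignal = 5, tRelax = 0,
                                                   recordEvery = 1))
  expect_true(is.na(transitionTime(prE, ens, targetLabel = "M", k = k)))
  expect_error(transitionTime(prE["final"], ens), "trajectory")
})

test_that("noise thresholds respect basin structure", {
  ts <- makeToggleSwitch()
  pT <- toggleParams()
  set.seed(96)
  ss <- findSteadyStates(pT, ts$topology, ensembleConfig(nICs = 60))
  expect_equal(nrow(ss$states), 2L)
  eState <- ss$states[which.max(ss$states[, "A"]), ]
  mState <- ss$states[which.max(ss$states[, "B"]), ]
  model <- list(model_id = 1L, params = pT,
                states = rbind(E = eState, M = mState))

  # an unclamped bistable system with D = 0 never escapes: no threshold
  res0 <- noiseThresholdScan(model, ts$topology,
                             stats::setNames(numeric(0), character(0)),
                             eState, mState, DGrid = 0,
                             protocol = protocolConfig(tSignal = 50),
                             nTrials = 3)
  expect_true(is.na(res0$D))
  expect_error(noiseThresholdScan(model, ts$topology,
                                  stats::setNames(numeric(0), character(0)),
                                  eState, mState, DGrid = numeric(0)),
               "empty")

  # 1-gene self-activation toy with known asymmetric basins: escape from
  # the basin whose stable point sits nearer the unstable point needs less
  # noise than escape from the deeper basin (matched seeds per grid value)
  g1 <- GRNTopology(nodes = "X",
                    edges = data.frame(source = "X", target = "X", sign = 1L))
  pX <- structure(list(G = c(X = 20), k = c(X = 1),
                       edges = data.frame(source = "X", target = "X",
                                          sign = 1L, lambda = 10,
                                          threshold = 8, hill = 4L)),
                  class = "RacipeParams")
  rhsX <- function(x) racipeRHS(c(X = x), pX, g1)[[1]]
  set.seed(97)
  ssX <- findSteadyStates(pX, g1, ensembleConfig(nICs = 40))
  expect_equal(nrow(ssX$states), 2L)
  lo <- min(ssX$states[, 1]); hi <- max(ssX$states[, 1])
  unstable <- stats::uniroot(rhsX, c(lo + 1e-3, hi - 1e-3))$root
  shallow <- if (unstable - lo < hi - unstable) "lo" else "hi"
  mdl <- list(model_id = 1L, params = pX,
              states = rbind(E = c(X = lo), M = c(X = hi)))
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8)
  prot <- protocolConfig(tSignal = 100)
  noClamp <- stats::setNames(numeric(0), character(0))
  set.seed(98)
  dLoHi <- noiseThresholdScan(mdl, g1, noClamp, c(X = lo), c(X = hi),
                              grid, protocol = prot, nTrials = 5)$D
  set.seed(98)
  dHiLo <- noiseThresholdScan(mdl, g1, noClamp, c(X = hi), c(X = lo),
                              grid, protocol = prot, nTrials = 5)$D
  dLoHi <- if (is.na(dLoHi)) Inf else dLoHi
  dHiLo <- if (is.na(dHiLo)) Inf else dHiLo
  if (shallow == "lo") expect_lte(dLoHi, dHiLo) else expect_lte(dHiLo, dLoHi)
})
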