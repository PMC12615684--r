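---
title: "Methods: dual-framework perturbation screening of GRNs"
author: "grnperturb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-framework perturbation screening of GRNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnperturb)
```

# Scope

`grnperturb` asks a single question of a signed, directed gene regulatory
network (GRN): *which small transcriptional perturbations move the system
from one stable phenotype to another?* It answers it twice, with two models
that share the topology but nothing else — a Boolean spin model whose noise
is a Metropolis pseudo-temperature, and an ensemble of randomized-parameter
ODE models with Ornstein–Uhlenbeck (OU) transcriptional noise. A screening
layer enumerates all one- and two-node clamp signals, measures the fraction
of simulations that complete an epithelial-to-mesenchymal transition (EMT),
and correlates efficacy across frameworks and with group betweenness
centrality of the clamped nodes. Agreement between two such different
abstractions is evidence that a prediction is a property of the network
rather than of a parameterization.

# The Boolean spin model

Each gene `i` carries a spin `s_i = ±1` (high/low expression). The topology
enters through the interaction matrix `J`, with `J[i, j] = ±1` the sign of
the edge `j -> i` and 0 otherwise. The *frustration* of a state is the
number of directed links it violates (`s_i J_ij s_j < 0`, each link counted
once); low-frustration states are the mechanically stable phenotypes of the
network, and for two-team EMT circuits they split into epithelial (E) and
mesenchymal (M) families.

Dynamics are random sequential Metropolis updates: a node is drawn uniformly,
the pseudo-energy change of flipping it is
`dE = +2 s_i * sum_j J_ij s_j`, and the flip is accepted with probability
`min(1, exp(-dE / T))`. One *unit time* is `N` update attempts. Three
conventions deserve comment:

* **Sign of `dE`.** The implemented sign makes a spin aligned with its local
  field stable, which is the only convention consistent with low-frustration
  states being long-lived. The opposite sign (under which aligned spins are
  maximally unstable) is selectable via `booleanConfig(deltaESign = -1)` so
  the choice is auditable rather than silent.
* **Zero-field ties.** `dE = 0` gives acceptance `min(1, e^0) = 1`: tie
  flips are always accepted, exactly as the formula dictates. At `T = 0`
  this makes the greedy limit well-defined.
* **Time bookkeeping.** Durations (`tc`, quench time) are in unit times, so
  results are comparable across network sizes.

A transition experiment is: find a starting E state (fresh random spins
annealed at `searchT` until frustration `<= 10`, accepted if the epithelial
score exceeds `+4`), clamp the signal nodes at their mesenchymal values, run
`tc` unit times at temperature `T`, release the clamp, quench for 10 unit
times at `T = 0.5`, and score success as a final epithelial score below
`-4`. The epithelial score is the annotation-weighted spin sum; the default
annotation scores three epithelial markers `+1` and three mesenchymal
markers `-1`, so the score ranges over `[-6, +6]` and the `±4` thresholds
demand near-saturated phenotypes. For unscored nodes a screen tries both
clamp directions and reports the better one. Because the model is globally
flip-symmetric, MET statistics mirror EMT statistics exactly; the test suite
checks this with matched random streams.

The starting-state search temperature defaults to the protocol temperature,
clamped into `(0.5, 4]` — annealing at very low `T` stalls in glassy
configurations and at high `T` never settles; within that window the choice
only affects search time, not the accepted states.

# The randomized ODE ensemble

Continuous dynamics follow shifted-Hill regulation. For gene `A` with
regulators `B_i`:

$$
\frac{dA}{dt} \;=\; \frac{G_A}{\prod_i \lambda_{B_iA}}
\prod_i \left( \lambda_{B_iA} + \frac{1 - \lambda_{B_iA}}
{1 + (B_i / B^0_{iA})^{n_{B_iA}}} \right) \;-\; k_A A ,
$$

where `G` is the maximal production rate, `k` the degradation rate,
`lambda` the regulatory fold change (`> 1` activation, `< 1` inhibition),
`B0` the regulation threshold and `n` an integer Hill coefficient. An
unregulated gene relaxes to `G/k`. Note that the leading normalization
divides by the fold changes of *all* regulators, so a gene with inhibitors
has maximum production `G / prod(lambda_inh) > G` when uninhibited; this is
the formula the package implements throughout (one consequence is that
heavily inhibited genes span very wide expression ranges, which the
threshold sampling below accounts for).

Instead of one parameterization, the package samples an ensemble
(`sampleParameters()`): `G ~ U(1, 100)`, `k ~ U(0.1, 1)`,
`n ~ U{1..6}`, `lambda ~ U(1, 100)` (activation) or `U(0.01, 1)`
(inhibition). Thresholds follow a *half-functional* convention: for an edge
from regulator `B`, `B0 ~ U(0.02, 1.98) × M_B` where `M_B` is the estimated
median level of `B`, so each link has roughly even odds of being above or
below threshold across the ensemble. `estimateMedianLevels()` computes
`M_B` by Monte Carlo: the unregulated level `G/k` modulated by one pass of
shifted-Hill factors from `B`'s own regulators (drawn at *their*
unregulated levels). A single flat constant is the fallback
(`medianLevel = 91.8`, the median of `G/k` under the default ranges); the
one-pass refinement matters because heavily inhibited genes would otherwise
receive thresholds their regulator never reaches, silencing whole arms of
the network. This estimate is deliberately one pass, not a fixed-point
iteration — it is a sampling convention, not a solved quantity, and it is
overridable per call.

Each model is integrated from `nICs` random initial conditions (log-uniform
between `0.01` and the per-gene cap `G/k` — spanning the reachable range on
the multiplicative scale) with fixed-step explicit Euler (`h = 0.1`) until
the derivative infinity norm drops below `1e-6` or `tMax = 200` time units
elapse; non-converged trajectories are excluded and counted. Endpoints equal
after rounding their `log1p` values to 2 decimals are collapsed to one
steady state. Rounding on the transformed scale (rather than raw) makes the
collapse relative — two states at 5000 and 5000.4 merge while 0.01 and 0.4
do not — which suits expression values spanning five orders of magnitude;
`ensembleConfig(dedupOnRaw = TRUE)` restores absolute rounding.

Pooled states are `log(1 + x)`-transformed and per-gene standardized
(sample sd; zero-variance genes map to 0 with a warning), and the transform
is stored so trajectories and endpoint states land in the same coordinates.
A Gaussian mixture (2 components, diagonal covariance) labels the states,
with the cluster count 2 cross-checked by mean silhouette width over
k = 2..6 (k-means labels substitute at any k where the mixture degenerates);
the cluster with higher mean `Cdh1` is named E. Models with exactly one E
and one M state form the bistable screening subset.

**Classifier self-consistency.** Perturbation outcomes are labelled by
k-nearest-neighbour (KNN, `k = 25`, Euclidean on processed coordinates,
ties broken toward M — a fixed rule rather than platform randomness)
classification against the pooled unperturbed states. When two clusters
overlap, a model's resting E state can itself classify as M, so a protocol
that does nothing would be scored as a transition. `bistableModels()`
therefore requires, by default, that each steady state KNN-classify to its
own cluster label; disable with `selfConsistent = FALSE`. This is a
screening-hygiene filter on model selection, not a change to the
classifier.

## Perturbations and noise

A signal clamps 1–2 genes, bit-identically, at their expression in the
model's *target* state (its M state for EMT) for `tSignal = 500` time
units; the clamp is then removed and the system relaxes deterministically
for `tRelax = 50` units before classification. Transcriptional noise, when
enabled, is an exact-update OU process per gene,

$$ U(t+h) = U(t)\,e^{-h/\tau} + D_g \sqrt{1 - e^{-2h/\tau}}\; z_t , $$

with correlation time `tau = 10` and stationary standard deviation
`D_g = D ×` (the gene's mean expression across the model's steady states),
so highly expressed genes receive proportionally more noise. `D` is named a
"noise variance" in parts of the field's literature but enters as a standard
deviation multiplier; the package consistently treats it as the stationary
sd. The OU value is added to the gene's *derivative* each Euler step
(`dA/dt = rhs_A + U_A`); adding it to the state directly is the recorded
alternative and gives smaller effective noise at the same `D`. Noise acts
only during the signal window (noise-only controls use the same window with
no clamp), and expression is floored at 0 after every step. Trajectories can
be sampled at fixed intervals for transition-time detection (earliest
sampled time classified as the target).

`noiseThresholdScan()` addresses a narrower question — given a *fixed*
clamp, how much noise is needed to move between the clamped system's
attractors — and therefore classifies endpoints by proximity (log1p
Euclidean) to the supplied candidate states rather than by ensemble KNN,
and omits the relaxation phase.

# Screening and analysis

`enumerateSignals()` yields all `N` singletons and `C(N, 2)` pairs (351
for a 26-node network). `signalEfficacy()` starts every bistable model in
its E state and reports the percentage ending in M; `efficacyMatrix()`
arranges per-signal results as a symmetric matrix with singletons on the
diagonal, and `rankCorrelation()` (Spearman, average ranks on ties)
compares frameworks and centrality. Group betweenness centrality is the sum
over ordered pairs of non-group nodes of the fraction of shortest directed
paths passing through at least one group member — unweighted, signs
ignored, endpoints excluded, no normalization. No installed graph library
exposes the group variant, so the package computes it with BFS path
counting; the test suite validates it against exhaustive shortest-path
enumeration with igraph.

PCA (`pcaProjection()`) operates on the processed state matrix; its stored
rotation projects trajectories for inspection, and `trajectorySummary()`
condenses a trajectory to mean E-group and M-group expression with clamped
genes reported separately.

# The synthetic network generators

Fixtures are generated in code so that everything is testable without
downloads. `makeToggleSwitch()` is the canonical bistable motif (mutual
inhibition plus self-activation, annotated `A = +1`, `B = -1`);
`makeRandomGRN()` samples seeded random signed digraphs;
`syntheticEmtNetwork()` is a 26-node, 100-edge EMT-like circuit built once
from the structural features commonly reported for published EMT GRNs of
that size: two mutually inhibiting teams (epithelial microRNAs and factors
vs mesenchymal transcription factors), Zeb1 as the largest hub (out-degree
11, self-activating), Snai1 second (out-degree 10, self-inhibiting), a
deterministic team-consistent fill to exactly 100 edges, and a six-marker
annotation (maximum epithelial score +6).

What the stand-in does and does not show: it reproduces the *qualitative*
phenomenology — E/M bistability in both frameworks, Zeb1 as the strongest
single signal, noise amplification of weak signals, a positive
efficacy–centrality rank correlation — so green engine tests on it validate
the machinery. It is **not** the published 26-node EMT network: its barriers
are shallower (noise-only switching is substantially more frequent) and all
edge-level quantities (exact centrality scores, per-signal percentages)
differ. Users holding the published `.topo` file and score table can load
them with `readTopo()` / `readAnnotation()` and run the identical protocol;
copies of the synthetic stand-in ship in `inst/extdata/` with `synthetic`
in the file names.

# Numerical choices and problem sizes

* Euler with `h = 0.1` matches the non-stiff relaxation dynamics
  (`k <= 1`, time constants `>= 1`) and keeps the deterministic and
  stochastic integrators structurally identical; steady states are accepted
  at residual `1e-6` and verified through the right-hand side in tests.
* The Metropolis engine and the Euler integrator live in C++ with sparse
  edge representations; all randomness is drawn from R's RNG, so a single
  `set.seed()` reproduces any pipeline exactly.
* The test suite and the acceptance script run the full protocol at reduced
  scale — ensembles of 200 models × 50 initial conditions, screens over all
  351 signals on ~30 bistable models, Boolean screens at 50–100 runs per
  signal — sizes chosen so the complete pipeline executes in minutes on one
  core while keeping binomial sampling error on reported percentages to a
  few points.

# Limitations

* Transcription-only abstraction: no epigenetics, signalling kinetics or
  post-translational regulation; edges are static and signs certain.
* The parameter ranges are generic rather than organism-calibrated, and the
  half-functional estimate is one-pass, not self-consistent.
* Fixed-step Euler is inappropriate for stiff parameterizations outside the
  sampled ranges; there is no continuation or bifurcation analysis.
* KNN labels depend on the pooled ensemble's coverage; sparse regions of
  state space inherit labels from distant neighbours (mitigated, not
  removed, by the self-consistency filter).
* The Boolean engine's single pseudo-temperature conflates all noise
  sources; only the ODE ensemble separates parameter heterogeneity from
  dynamical noise.
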