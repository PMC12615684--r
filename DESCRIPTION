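Package: grnperturb
Title: Perturbation Screening of Gene Regulatory Networks with Boolean and
    ODE Ensemble Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates perturbation-induced state transitions in signed gene
    regulatory networks with two complementary engines: a Boolean spin model
    with Metropolis pseudo-temperature dynamics, frustration-based stable-state
    search and clamp/quench transition protocols; and an ensemble of
    randomized-parameter ordinary differential equation models with
    shifted-Hill regulation, steady-state enumeration, Gaussian-mixture E/M
    clustering and Ornstein-Uhlenbeck transcriptional noise. A screening layer
    enumerates one- and two-node clamp signals, quantifies transition efficacy
    across both frameworks, and relates efficacy to group betweenness
    centrality of the perturbed nodes. Designed around epithelial-mesenchymal
    transition (EMT) circuits but applicable to any signed directed topology.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
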