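Package: parbsbm
Title: Stochastic Binding Model of ParB Partition Complexes on Supercoiled
    DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo simulation of circular bacterial DNA as a
    self-avoiding rod-like chain (bending and torsional elasticity,
    hard-core excluded volume, crankshaft moves, simulated-annealing
    supercoiling schedule), ensemble observables (radius of gyration,
    parS-distance distributions, local writhe, plectoneme branch
    counting), and the Stochastic Binding Model converting conformational
    ensembles and a ParB cluster concentration profile into a non-specific
    DNA binding profile. Includes grid fitting of model profiles against
    ChIP-seq style coverage data and a synthetic-data generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
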