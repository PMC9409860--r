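Package: perturbnet
Title: Kinase Network Reconstruction from Inhibitor-Perturbation RPPA Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs causal kinase-signalling networks from
    inhibitor-perturbation reverse-phase protein array (RPPA) data by
    Bayesian Modular Response Analysis (BMRA): per-node sparse regression
    over log2 fold-change global response matrices with spike-and-slab
    variable selection under a Zellner g-prior, sampled by Gibbs. Builds
    group consensus networks, tests edges for sensitive-versus-resistant
    differences, compares basal activity states, and scores drug-combination
    synergy by the Chou-Talalay median-effect model and Loewe additivity.
    Includes a synthetic-data generator that simulates RPPA-like perturbation
    datasets from known ground-truth networks so that every stage of the
    pipeline can be validated against known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
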