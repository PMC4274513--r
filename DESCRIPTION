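Package: primatenet
Title: Efficiency, Centralisation and Modularity of Primate Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of weighted, symmetrized primate
    association networks. Computes per-group network statistics (edge density,
    diameter, Global Efficiency, Average Dyadic Efficiency, eigenvector-based
    centralisation index, maximum modularity), generates synthetic cohorts of
    groups with controllable centralisation and modularity nested in a
    taxonomy with an ultrametric species tree, and runs the comparative
    statistics used in cross-species studies of network efficiency:
    hierarchical mixed models with genus-within-family random effects (REML or
    Bayesian MCMC), variance components, Pearson and partial correlations
    under step-down sequential Bonferroni correction, Brown-Forsythe variance
    homogeneity tests, and Blomberg's K with a permutation test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    ape,
    lme4,
    lmerTest,
    coda,
    rjags,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    car,
    optparse,
    withr
Config/testthat/edition: 3
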