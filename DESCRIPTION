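Package: svysim
Title: Design-Based Simulation of Two-Stage Cluster Sampling for Household Health Surveys
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for design-based Monte Carlo evaluation of household survey
    sample designs. Generates a hierarchical finite population (strata,
    clusters, households, individuals) with a four-level Gaussian outcome,
    draws replicated samples under a conventional stratified systematic
    cluster design with a constant number of clusters per stratum and under an
    alternative two-stage design selecting clusters with probability
    proportional to household counts followed by simple random sampling of
    households, computes design-weighted (Hajek) estimates of means and
    proportions, and summarizes estimator accuracy as root mean squared error
    against the known population truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
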