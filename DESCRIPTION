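Package: oncogrid
Title: Agent-Based Lattice Tumor Growth and In Silico Combination Therapy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of avascular tumor growth on a
    two-dimensional cell lattice, with proliferating, quiescent and necrotic
    tumor layers and immune (natural killer and cytotoxic T) agents that search
    for and engage proliferating tumor cells. Provides per-iteration tumor
    structure statistics (pure tumor growth fraction, growth fraction, necrotic
    fraction, mean radii and rim thickness), virtual-patient dose-grid
    experiments in which qualitative High/Medium/Low drug doses are mapped onto
    model parameters, and a combinatorial feature-scoring algorithm (DTG, STG,
    DMP, SMP, DPD) that enumerates and ranks candidate combination-therapy
    sets by the diversity of their target groups, action mechanisms and
    physical dimensions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
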