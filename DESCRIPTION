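Package: collapsenet
Title: Network Model of Societal Complexity, Resilience and Collapse
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Agent-based simulation of a stylized society on an Erdos-Renyi
    network in which stochastic shocks to energy production trigger the
    growth of a non-producing administrator class, following Tainter's
    theory of collapse through diminishing marginal returns on complexity.
    Includes the stochastic micro-model with optional random social
    mobility ("exploration"), a deterministic mean-field approximation of
    the administrator dynamics with fixed-point and stability analysis,
    the critical exploration threshold 1/N, and right-censored
    survival-time experiments (ensembles, histograms, parameter sweeps
    over link density, productivity and exploration probability).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
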