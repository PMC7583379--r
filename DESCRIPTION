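Package: lakeshift
Title: Depth-Resolved Simulation of Shallow-Lake Regime Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional (hypsograph-based) shallow-lake ecosystem
    simulator with fully closed nitrogen and phosphorus cycles, built to
    study regime shifts between turbid, phytoplankton-dominated and clear,
    macrophyte-dominated states. The water column is discretised into
    bottom-refined layers, each with its own sediment compartment, so light
    at the sediment surface and benthic area vary with depth. Sources and
    sinks are integrated with a positivity-preserving, mass-conserving
    Modified Patankar scheme. The package includes the full bifurcation
    workflow (external phosphorus-load multiplier grids, looped baseline
    forcing, oligotrophication and eutrophication branches, load-response
    curves and hysteresis-range detection), stepwise differential-evolution
    autocalibration against sparse depth-pooled observations, and a
    deterministic synthetic-data generator (morphometry, meteorology,
    inflow, monitoring observations) so the whole pipeline runs with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
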