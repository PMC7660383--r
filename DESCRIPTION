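Package: symte
Title: Symbolic Conditional Transfer Entropy for Monthly Public-Health Time-Series
Version: 0.1.0
Authors@R: person("DSL", "Maintainers", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Wiener-Granger causal analysis of monthly count time-series through
    binary symbolic dynamics. Provides plug-in estimators of entropy, transfer
    entropy and conditional (partial) transfer entropy with an exact-pmf oracle,
    seasonal adjustment and symbolization of monthly series, mass-shooting
    event-list encoding, one-dimensional k-means partitioning of legal
    environments, geodesic nearest-neighbour interaction series,
    structure-preserving stratified permutation tests with population-weighted
    group aggregation, three orchestrated state-level studies with
    conditional-probability maps, and seeded synthetic-data generators with
    planted causal structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    datasets,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
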