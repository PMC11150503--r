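Package: hexforage
Title: Maximum-Entropy Replicas and Information Analysis of Collective Ant
    Foraging on Hexagonal Arenas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spatiotemporal organisation of collective
    ant foraging on hexagonal channel arenas. Builds honeycomb lattice arenas
    and food-placement scenarios, generates synthetic colony foraging trials
    (three-phase dynamics with group recruitment and trail memory), converts
    tracks to binary node-occupancy time series, quantifies spatial
    organisation through pairwise mutual information, fits pairwise
    maximum-entropy (inverse Ising) "computational replicas" of colonies by
    node-wise pseudolikelihood, samples them with Glauber dynamics, and runs
    in-silico first-passage food-detection experiments comparing replicas
    trained under deterministic and stochastic food conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
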