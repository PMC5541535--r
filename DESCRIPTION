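Package: dirmatch
Title: Movement-Influence Networks from Sparse Animal GPS Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed movement-influence networks in group-living
    animals from sparse, asynchronous GPS fixes. Each animal's observed
    unit direction of travel is regressed, in a Bayesian framework with
    regularised priors, on unit vectors toward every other group member,
    toward the group centroid, and along its previous heading ("direction
    matching"); coefficients whose 99% highest-posterior-density intervals
    exclude zero become weighted directed edges. The package fits the full
    and group-only models with WAIC comparison, relates dyadic influence to
    dominance-rank difference with a varying-intercept model and posterior
    R-squared, decomposes the attraction network with a weighted k-shell
    algorithm, and tests core/periphery magnitude against an Erdos-Renyi
    permutation null. A seeded attraction-repulsion agent-based simulator
    with an observer-sweep degradation model makes every stage verifiable
    by parameter recovery.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
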