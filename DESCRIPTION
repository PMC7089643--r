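Package: seastage
Title: Seasonal Consumer-Resource Dynamics with Size and Stage Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates seasonally reproducing consumer-resource systems with
    two interchangeable population representations: a cohort-based,
    physiologically structured population model (PSPM) in which individuals
    grow continuously between annual reproduction pulses, and a low-dimensional
    stage-structured biomass approximation with one or more juvenile stages.
    Both models share a common bioenergetic core (Holling type II ingestion,
    mass-specific maintenance, starvation mortality, capital-breeding storage)
    and a semi-discrete season engine that integrates continuous within-season
    dynamics and applies instantaneous maturation and reproduction maps.
    Includes tools for bifurcation sweeps with warm starts, time-averaged and
    post-reproduction summaries, reproduction-gap statistics, and cross-model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
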