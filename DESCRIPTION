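Package: coevocycles
Title: Eco-Evolutionary Predator-Prey Coevolution Cycles and Their Geber
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a coevolutionary predator-prey model in which a prey
    defense trait and a predator offense trait evolve along the fitness
    gradient while biomasses follow Rosenzweig-MacArthur dynamics with a
    Holling type II functional response. Provides the effective prey biomass,
    the Geber-method decomposition of fitness change into contributions of
    biomass and trait dynamics, Fourier cross-spectrum phase-lag estimation
    for classifying antiphase versus quarter-lag predator-prey cycles,
    Spearman component correlations, and a parameter-sweep pipeline that
    associates component correlations with the phase relationship across
    grids of adaptation speeds or trait costs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
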