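Package: rvprice
Title: Reproductive Value, Fitness and Price Equations under Stochastic
    Demography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying natural selection in finite class-structured
    populations with a Markov environment and fluctuating class distribution.
    Models reproduction as a finite-support stochastic kernel with class-based
    ploidies and single-coreplicon transmission accounting, solves reproductive
    value as the fixed point of the associated transition operator, computes
    Williams' reproductive value and Fisherian individual fitness over a single
    selective ("Taylor") year started from the neutral process's ergodic
    distribution, and verifies the exact identities of the theory (martingale
    property of lineage reproductive value, class-structured Price equations,
    and fundamental-theorem decompositions) by exhaustive enumeration or Monte
    Carlo on built-in fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
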