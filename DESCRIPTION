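Package: strawcycle
Title: Multi-Objective Allocation of Water, Nitrogen and Straw in
    Circular Agroecosystems
Version: 0.1.0
Authors@R:
    person("Agro", "Systems Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for planning irrigation water, nitrogen fertilizer and
    crop-straw reuse (field return, biochar, electricity generation, sale)
    in a two-stage circular cropping system.  Implements a Jensen-type
    crop water production model with quadratic nitrogen response, a
    straw-to-energy and straw-to-biochar conversion chain, net economic
    benefit accounting, a composite crop quality score, green/blue/gray
    water footprints and a greenhouse-gas inventory with soil carbon
    sequestration.  The four objectives are scalarized by fuzzy linear
    memberships (max-min) and solved by a multistart penalized
    quasi-Newton method; a brute-force grid oracle is provided for
    verification.  Includes Pearson type III hydrological frequency
    analysis with Monte Carlo year classification, triangular
    intuitionistic fuzzy parameters, AHP/entropy/game-theoretic
    indicator weighting, coupling coordination-degree evaluation, and a
    synthetic-data generator that emulates the assumed field-trial
    structure so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
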