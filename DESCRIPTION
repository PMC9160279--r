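Package: biogasim
Title: Biogas Potential, Batch Digestion Kinetics and Electricity
    Estimation from Feedstock Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting and analysing biogas production from
    organic feedstocks such as wastewater sludge. Converts ultimate
    (elemental) and proximate analyses into an empirical molecular
    formula, balances the Buswell-Boyle digestion stoichiometry to
    predict theoretical methane, carbon dioxide, ammonia and hydrogen
    sulfide yields, estimates higher and lower heating values with the
    Dulong correlation, simulates and fits batch digestion kinetics
    (modified Gompertz and first-order models) with a cardinal
    temperature response, generates synthetic triplicate optimization
    experiments across pH, loading ratio and temperature, and estimates
    the electricity generation potential of the produced methane.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
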