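Package: n2otracer
Title: Gross Nitrogen Transformation and N2O Production Rates from 15N
    Tracer Incubations
Version: 0.1.0
Authors@R:
    person("Estuarine Biogeochemistry", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates gross nitrogen transformation rates (ammonia
    oxidation, nitrite oxidation, nitrate reduction) and N2O production
    rates from 15N labelled time-course incubations, with binomial
    isotopologue (44/45/46 N2O) accounting, first-order error
    propagation, air-sea N2O flux computation from solubility and wind
    speed parameterizations, and derived statistics: N2O yields, source
    partitioning between oxidative and reductive pathways,
    particle-size-spectrum summaries and depth-integrated
    production-to-flux ratios. Includes a synthetic incubation generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
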