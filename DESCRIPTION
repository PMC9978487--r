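Package: bactclim
Title: Climate-Change Projections of Marine Heterotrophic Bacteria
Version: 0.1.0
Authors@R:
    person("bactclim", "developers", email = "bactclim@example.org",
           role = c("aut", "cre"))
Description: A mechanistic box model of marine heterotrophic bacterial
    carbon dynamics (free-living and particle-attached fractions with
    Monod/Contois substrate limitation and Q10 temperature scaling),
    together with a seeded synthetic generator of gridded historical and
    SSP-scenario forcing fields, area-weighted regional composite and
    change statistics, a first-order Taylor attribution of changes in DOC
    uptake into temperature versus substrate control, Arrhenius-type
    temperature analysis, and model-observation skill scoring with
    microbial unit conversions (cell-carbon and thymidine conversion
    factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
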