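Package: vegcarb
Title: Coupled Spatial Vegetation and Long-Term Carbon-Cycle Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale simulator of the coupling between plant geographic
    range and the long-term carbon cycle. A fast gridded vegetation kernel
    computes net primary productivity and steady-state biomass for three
    plant functional types on a latitude-longitude grid; per-cell biotic
    enhancement of silicate and carbonate weathering and vegetation-scaled
    organic-carbon burial close a single atmosphere-ocean carbon reservoir,
    so that steady-state atmospheric CO2 responds to the habitable range of
    plants. Includes generators for synthetic supercontinent and dispersed
    paleogeographies with zonal climates and arid continental interiors, an
    adaptive-timestep coupler that spins vegetation to steady state inside
    every carbon-cycle step, and an ensemble driver for parameter
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
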