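Package: shallowcrop
Title: Daily Crop-Water Simulation over Shallow Groundwater
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Daily-timestep simulator coupling a four-zone soil water balance
    (Thornthwaite-Mather percolation accounting and the Gardner analytical
    solution for capillary rise from a dynamic shallow water table) with an
    EPIC-style maize growth model (heat-unit phenology, leaf-area dynamics,
    radiation-use-efficiency biomass, harvest-index yield) and a canopy- and
    moisture-driven actual-evapotranspiration module. Includes an FAO-56
    Penman-Monteith reference evapotranspiration routine, a synthetic weather
    generator emulating the arid Hetao (Inner Mongolia) climate, a deficit
    irrigation x groundwater-depth scenario engine with water-productivity
    summaries, and an evaluation toolkit (fit statistics, one-at-a-time
    parameter sensitivity, d-factor uncertainty).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
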