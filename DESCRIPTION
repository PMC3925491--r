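Package: gwex
Title: Mapping Groundwater-River Exchanges from Hydraulic and Biological Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and quantifies water exchanges between an alluvial
    aquifer and a river corridor by combining three independent indicators:
    Darcy-law exchange fluxes estimated along bank polylines from
    triangulated irregular network (TIN) models of the piezometric and
    river-stage surfaces; groundwater-obligate (stygobite) invertebrate
    richness and abundance in interstitial habitats; and macrophyte-based
    trophic and groundwater-influence indices derived from species
    ecological profiles. Includes a zone-overlay stage that issues
    convergence verdicts between the three maps, seed-reproducible
    synthetic-valley and community generators with closed-form oracles,
    CSV/GeoJSON readers and writers, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
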