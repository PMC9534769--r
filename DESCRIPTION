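Package: pco2phen
Title: Seasonal Phenology of Surface-Ocean pCO2 Under Rising Atmospheric CO2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how the seasonal timing of surface-ocean CO2
    partial pressure (pCO2) and related carbonate-system variables changes as
    atmospheric CO2 rises, with a focus on polar oceans. Provides a seawater
    CO2-system equilibrium solver with numerical driver sensitivities,
    Taylor-expansion decompositions of monthly pCO2 anomalies into thermal,
    haline, alkalinity and dissolved-inorganic-carbon contributions (including
    a freshwater-separated variant and an incremental end-of-century
    procedure), a climate-CO2 separation attributing decadal change to
    changed sensitivities versus changed driver anomalies, phenology
    diagnostics (months of annual high/low, three-stage classification,
    high/low crossover detection, sea-ice retreat and growth dates, debiased
    summer maxima), idealized polar grid bookkeeping, and a seeded generator
    of Earth-system-model-like monthly surface fields with a recorded truth
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
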