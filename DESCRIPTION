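Package: colimitr
Title: Colimitation of Autotrophic Growth by CO2- and HCO3--Dependent
    Carboxylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state model of inorganic-carbon (Ci) physiology in
    autotrophic bacteria, in which growth is colimited by rubisco-catalyzed
    CO2 fixation and HCO3--dependent anabolic ("bicarboxylation")
    carboxylation. Provides carbonate-system chemistry, a linear two-pool
    membrane-flux cell model with carbonic anhydrase (CA) and energized Ci
    uptake, Liebig-minimum growth prediction and regime classification,
    parameter-sweep engines (CA/uptake futile-cycle leakage, CO2 depletion,
    CO2-pump permeability bounds, CO2 titrations), scoring of CO2-concentrating
    mechanism (CCM) acquisition trajectories under declining atmospheric CO2,
    a barcoded-transposon competition fitness statistic, and synthetic-data
    generators (barcode count tables and logistic growth curves) for
    end-to-end testing without external data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
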