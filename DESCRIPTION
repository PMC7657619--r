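Package: ppiflux
Title: Chemostat Flux Accounting and Pyrophosphate Bioenergetics for
    Anaerobic Thermophiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state chemostat flux accounting for cellobiose-fermenting
    anaerobes such as Clostridium thermocellum and Thermoanaerobacterium
    saccharolyticum. Closes carbon and nitrogen balances (including CO2
    inferred from fermentation stoichiometry), computes specific production
    rates per gram of cell nitrogen, manipulates reaction stoichiometry with
    exact rational arithmetic to form pathway nets (pyrophosphate-dependent
    glycolysis, pyruvate-phosphate dikinase, the malate shunt, tRNA charging),
    and budgets anabolic pyrophosphate supply against catabolic demand with
    the resulting ATP requirement and maximum biomass yield on ATP. A
    synthetic steady-state generator with known ground-truth fluxes supports
    validation without external data.
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
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
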