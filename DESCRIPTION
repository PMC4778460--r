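Package: aerohab
Title: Thermal Habitat Suitability from Aerobic Metabolic Scope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate aerobic metabolic scope of fishes from
    intermittent-flow respirometry traces, fit species-specific thermal
    performance curves (exponential standard metabolic rate and a skewed
    maximal metabolic rate curve), and project thermal habitat suitability
    and a two-species coexistence factor over gridded daily temperature
    fields for present-day and delta-method warming scenarios. Includes a
    synthetic-data module that emulates the full experimental design
    (multi-temperature acclimation groups, respirometry protocol, and
    decade-long daily temperature fields) with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
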