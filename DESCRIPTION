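Package: noctura
Title: Diurnal-Preference Phenotyping and Quantitative Genetics of Fly
    Locomotor Rhythms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Turns Drosophila activity-monitor recordings into
    diurnal-preference phenotypes and genetic conclusions. Provides readers
    for DAM-style monitor files and tidy CSV, light-regime annotation
    (including subjective day/night in constant darkness), the night/day
    activity ratio (ND ratio), rhythmicity screening by Fisher's exact
    g-test, free-running period estimation by the Sokolove-Bushell
    chi-square periodogram (with a Lomb-Scargle cross-check), circular
    acrophase statistics, five-minute-immobility sleep scoring, light
    masking contrasts and light-pulse phase shifts. On the genetics side it
    estimates selection differentials, realized heritability from
    truncation-selection experiments (with a correction for sib-mating
    designs and a parametric-bootstrap drift variance), parent-offspring
    regression heritability, and runs modified quantitative complementation
    tests. An infinitesimal-model simulator generates heritable
    diurnal-preference populations, Poisson actograms, selection
    experiments, parent-offspring families and complementation tables for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
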