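Package: tropirep
Title: Representativeness of Field Sampling and Citation Across Tropical
    Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well a geocoded literature database of
    field sampling locations represents the environmental conditions of the
    terrestrial tropics. Reads and validates per-location literature records,
    allocates article citations equally across sampling locations, excludes
    urban and agricultural habitats, clips records to a buffered tropical
    biome domain, and summarizes sampling and citation shares and densities
    per biome. Compares sampling and citation frequencies against background
    environmental frequencies in two-dimensional covariate space, and fits a
    presence/pseudo-absence ensemble (generalized additive model, random
    forest, gradient-boosted trees) whose cell-wise median probability maps
    sampling representativeness, with permutation cross-validated AUC and
    covered-area summaries. Includes a synthetic-data generator (correlated
    random-field covariate stacks, biome partitions, preferentially sampled
    literature tables) so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
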