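Package: grazemetry
Title: Anatomy, Movement and Diet-Selection Allometry of Grazing Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative grazing studies of cattle breeds on
    heterogeneous pastures: claw-base area and static-pressure arithmetic,
    metabolic live-weight (W^0.75) stocking calculations, GPS trajectory and
    pedometer summaries, 5 m grid occupancy with Camargo evenness of space
    use and habitat-covariate regressions, bite-record diet composition with
    Briemle forage-quality scoring and Pielou selection evenness, and
    standardized major axis (SMA) allometric line fitting with multi-group
    slope, shift and elevation tests. Includes a seeded synthetic-herd
    generator (biased correlated random walks on a gridded pasture, Poisson
    pedometer model, softmax diet selection) for end-to-end testing and
    parameter-recovery studies.
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
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
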