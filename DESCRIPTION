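Package: stratnet
Title: Stratified Partial-Correlation Networks for Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates significance-sparsified partial-correlation networks
    for strata of a clinical cohort (for example patients with and without
    comorbid food addiction), computes node centrality, community structure
    and global graph metrics, runs a descriptive group-comparison battery
    with Finner's step-down multiple-testing correction, and ships a seeded
    synthetic-cohort generator with a planted conditional-dependence
    structure so the whole pipeline can be validated without patient data.
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
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
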