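Package: hervmb
Title: Locus-Specific Endogenous Retrovirus RNA Markers for Medulloblastoma Subgrouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of locus-specific human endogenous retrovirus derived
    RNAs (hervRNAs) in medulloblastoma cohorts: filtering of independently
    expressed hervRNAs from passively co-transcribed ones via a nearby
    driver-gene rule (1 Mbp window, paired signed-rank test, Pearson r > 0.4),
    selection of subgroup-specific binary hervRNA classifiers under four
    criteria, single-linkage genomic clustering of classifiers (200 kbp gap)
    with cluster-positivity voting for subgroup assignment, and integration
    of promoter CpG methylation with hervRNA expression. Includes a seeded
    synthetic-cohort generator that emulates the statistical structure of a
    medulloblastoma hervRNA study so the full pipeline is testable without
    controlled-access data.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
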