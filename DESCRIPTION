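Package: geneburden
Title: Rare-Variant Gene-Burden Enrichment Testing with Capture-Adjusted Loads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for gene-based collapsing analysis of
    rare coding variants in case-control exome cohorts. Filters variants to a
    qualifying set (coding or splice-site, rare in population databases,
    predicted pathogenic by loss-of-function class or SIFT/PolyPhen-2 scores),
    computes per-gene mutational loads adjusted for platform-specific capture
    rates, tests enrichment with two-sided Fisher exact tests and Bonferroni
    correction against internal cohorts or external summary-statistic controls,
    benchmarks false positives with random control gene sets, and ships a
    seeded synthetic-cohort generator with known ground truth so the whole
    pipeline is testable end to end without external data.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
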