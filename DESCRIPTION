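Package: novascore
Title: Dual-Mode NOVA Classification and Nutri-Score Profiling for Branded Food Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of packaged foods into the four NOVA
    food-processing groups using either the product name alone (the "generic"
    database setting) or the product name plus the on-package ingredient list
    (the "branded" setting), together with an FSAm-NPS nutrient-profiling
    engine that assigns five-level Nutri-Score grades. Includes cross-tabulation
    of classification flows between the two modes, fold changes and
    reclassification shares, nonparametric group comparisons
    (chi-square, Kruskal-Wallis, pairwise Mann-Whitney with Bonferroni
    correction), and a seeded synthetic branded-food-database generator with
    known ground-truth classes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
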