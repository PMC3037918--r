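Package: markerscreen
Title: Rank-Based Disease Expression Screening and Tissue-Microarray
    Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrative-genomics candidate biomarker screen and its
    validation statistics. Scores genes across a multi-dataset disease
    expression compendium with a per-sample rank-normalized expression
    change bounded in [-1, +1], applies a filter cascade (selective
    upregulation in a target disease but not comparators, intersection
    with a susceptibility gene list, restriction to biofluid-detectable
    proteins), and analyses tissue-microarray immunohistochemistry
    cohorts with contingency tables, Fisher's exact test, chi-square,
    tie-corrected Wilcoxon rank-sum and Kruskal-Wallis tests, Bonferroni
    adjustment, Woolf odds-ratio intervals and logistic regression.
    Seeded synthetic generators emulate the compendium, gene lists and
    cohort so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
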