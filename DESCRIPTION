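Package: trophon
Title: Trophic Niche Partitioning Analysis for Stomach-Content Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of trophic niche partitioning between
    sympatric fish populations from stomach-content survey data: diet
    composition indices (frequency of occurrence, volumetric frequency,
    index of feeding importance), Levin's standardized niche breadth and
    Pianka's niche overlap with the conventional low/moderate/high
    classification, RA3 randomization null models with Monte-Carlo tail
    probabilities, nycthemeral activity statistics (chi-square tests with
    Yates correction, G-tests, size-structure comparisons), and a
    synthetic stomach-content generator so every pipeline stage can be
    exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
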