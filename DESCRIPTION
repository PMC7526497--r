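Package: switchjxn
Title: Repair-Pattern Analysis of Class-Switch Recombination Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Breakpoint calling of Sanger-length class-switch recombination
    (CSR) junction reads against donor and acceptor switch-region references,
    scoring of perfectly matched junctional microhomology, untemplated
    insertions and sequential-switching footprints, classification of
    junctions into the four canonical repair-pattern categories (direct
    end-joining, small insertions, 1-6 bp and >=7 bp microhomology),
    mutational-signature analysis of double-strand-break reporter junctions,
    and the cohort-level statistics (per-category Pearson chi-squared,
    Mann-Whitney U) used to contrast classical and alternative end-joining
    usage between patient and control cohorts. Includes a synthetic-data
    generator that emulates repeat-rich switch regions and junction formation
    under configurable end-joining regimes with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
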