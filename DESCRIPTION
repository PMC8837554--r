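Package: migwas
Title: Post-GWAS Meta-Analysis, Risk-Locus Definition and Subtype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream stages of a multi-cohort genome-wide
    association meta-analysis of a binary trait with two clinical subtypes.
    Harmonizes per-cohort summary statistics to a reference panel and applies
    variant-level quality control, pools cohorts by inverse-variance weighted
    fixed-effect meta-analysis with effective-sample-size filtering and genomic
    inflation diagnostics, defines risk loci by greedy linkage-disequilibrium
    clumping with block spanning and interval merging, performs stepwise
    approximate conditional analysis from summary statistics and reference LD,
    and classifies risk alleles as subtype-specific, shared or null with a
    four-model Bayesian comparison on bivariate effect sizes. A block-LD
    synthetic-data generator emulates multi-cohort summary statistics so that
    every stage is testable without access-controlled consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
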