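Package: karyohybrid
Title: Karyotype and Plastome Evidence for Natural Hybrid Parentage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies reciprocal natural hybrids from cytological and
    chloroplast-genome evidence. Computes per-chromosome and complement
    karyotype statistics from arm measurements (karyotype formula,
    Romero Zarco A1/A2 asymmetry indices, Stebbins class), predicts F1
    complements under balanced-gamete meiotic additivity and screens
    candidate parent pairs, partitions circular plastomes into their
    quadripartite LSC/IRb/SSC/IRa structure with junction-gene reports,
    calls substitutions and short indels between near-identical plastomes
    by anchor-chained collinear alignment, scans and compares chloroplast
    microsatellite (cpSSR) catalogues, clusters taxa by UPGMA on
    standardized trait distances, and combines maternal plastome
    assignment with karyotype additivity into a cross-direction report.
    A seeded synthetic-data generator emulates metaphase measurement
    tables and quadripartite plastomes so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    withr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
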