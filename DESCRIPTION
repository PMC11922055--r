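Package: stallkit
Title: Simulation and Analysis of tRNA Acetylation, Ribosome Stalling, and
    Codon-Biased Translation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect N4-acetylcytidine (ac4C) in tRNA from
    reduction-dependent C-to-T misincorporation sequencing, quantify tRNA
    isodecoder abundance with tolerance for modification-induced mismatches,
    measure codon-resolution ribosome and disome (collision) occupancy from
    footprint libraries, compute codon-usage and amino-acid-family skew
    statistics, and evaluate closed-form molecular assays (Sanger
    misincorporation, delta-delta-Ct charging and expression, densitometry,
    and Mendelian breeding-ratio tests). A fully seeded synthetic-data
    generator emulates each data-generating process so every stage of the
    pipeline can be validated by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
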