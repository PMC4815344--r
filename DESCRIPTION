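Package: snviface
Title: Minor Allele Frequency and the Structural Location of Variants on
    Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps nonsynonymous single-nucleotide variants onto protein
    complex structures and analyses how they distribute across
    protein-protein interface regions as a function of minor allele
    frequency. Implements a deterministic Shrake-Rupley accessible surface
    area engine, the Levy core/rim/support interface classification from
    relative solvent accessibility and its change on binding, variant to
    chain mapping by global sequence alignment, rare/intermediate/common
    allele frequency stratification, contingency-table enrichment tests,
    per-amino-acid relative frequency statistics, transition/transversion
    substitution typing, and a fully seeded synthetic-data generator with
    depletion parameter recovery for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    bio3d,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
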