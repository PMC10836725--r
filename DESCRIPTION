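Package: poolscreen
Title: Design and Deconvolution of Pooled Minigene Antigen Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for genetically encoded antigen screens:
    tiling of proteins into overlapping minigene fragments, programmed
    substitutions (e.g. deamidation edits), construct assembly with leader and
    linker sequences, hierarchical fragment refinement toward minimal epitope
    intervals, constrained codon-optimized backtranslation to synthesizable
    DNA, combinatorial pooled-array design with guaranteed single-target
    deconvolution, and screen readout analysis (Overton percent-positive,
    well Z-scores, replicate aggregation, positive-well calling and design
    inversion). A synthetic-screen simulator generates every input with known
    ground truth so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
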