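Package: barnyardqc
Title: Quality Control for Mixed-Species Single-Cell RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An instrument-free toolkit for quality control of barnyard
    (two-species mixture) single-cell RNA-seq experiments. Extracts cell
    barcodes and UMIs from fixed-layout read pairs, detects cell-associated
    barcodes on the barcode rank curve with a distance-based knee method,
    deduplicates UMIs into sparse gene-by-cell count matrices, downsamples
    raw reads to a target depth, computes per-barcode species purity and
    hetero-species multiplet rates with total multiplet-rate extrapolation,
    applies standard cell and gene filters with counts-per-ten-thousand log
    normalization, and provides experiment-design calculators for bead-cell
    coupling yields and hydrogel complex spacing. Includes a synthetic
    barnyard experiment generator with known ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
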