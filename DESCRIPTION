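Package: rcdscan
Title: Genome Scans for Reinforcement and Reproductive Character Displacement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based genome scan for reproductive character displacement
    in a two-species, four-population design (allopatric/parapatric pairs of
    two hybridising species). Defines variable-length genomic windows from
    smoothing-spline inflection points of per-site minor allele frequencies,
    computes windowed Hudson F_ST, invariant-aware D_XY and Tajima's D,
    estimates per-window two-component ancestry for the introgressed
    population, and calls candidate reinforcement windows by combining a
    permutation null for the parapatric-minus-allopatric divergence
    difference with Tajima's D and ancestry cutoffs. Downstream annotation of
    candidate genes covers population-unique variants, coding-effect
    classification, B-SIFT scoring and transcription-factor motif uniqueness.
    A synthetic-data module generates four-population genotype data with
    planted reinforcement windows so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
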