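Package: clonoverge
Title: Paired Single-Cell TCR Clonotyping and Convergent Recombination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for paired single-cell TCR repertoire analysis:
    ingestion of 10x-style filtered contig annotation tables, hashtag
    (cell-hashing) normalization and demultiplexing, paired-chain clonotype
    calling at the nucleotide level, amino-acid-level TCR-type grouping,
    V(D)J junction decomposition into germline V/P/N/D/P/J parts, and
    convergent-recombination and compartment-composition reporting. Ships a
    germline-referenced V(D)J recombination simulator (trimming, P additions,
    N insertions, power-law clonal expansion, hashtag multiplets, label
    enrichment) that generates ground-truth repertoires so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
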