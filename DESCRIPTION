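Package: damidcall
Title: Targeted DamID Occupancy Tracks, Expression Calling and Regulator
    Integration
Version: 0.1.0
Authors@R:
    person("Alex", "Marsh", email = "alex.marsh@example.org",
           role = c("aut", "cre"))
Description: Analysis of targeted DamID (TaDa) sequencing data at native
    GATC-fragment resolution: builds GATC fragment maps from a genome,
    quantifies normalized log2 Dam-fusion over Dam-only occupancy tracks,
    calls gene-level RNA polymerase II occupancy ("expression") with a
    permutation false-discovery rate, classifies genes as cell-type
    specific or enriched, calls significant transcription-factor binding
    peaks and their gene-body target sets, and integrates expression
    specificity with multiple binding profiles to prioritize candidate
    regulators. Includes a negative-binomial simulator with planted
    ground truth for end-to-end validation, plus a subcommand-style
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    data.table,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
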