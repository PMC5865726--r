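Package: rapscan
Title: Genomic SELEX Peak Calling and RNA Polymerase II Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls RNA-polymerase-binding aptamer (RAP) peaks from genomic
    SELEX mate pairs with a Gaussian-smoothed derivative peak finder,
    characterises the genomic context of the peaks with length-preserving
    randomization enrichment tests, associates RAP presence with host-gene
    transcript abundance through exact Poisson segment tests, and detects
    RAP-associated intragenic drops in RNA polymerase II occupancy from
    strand-specific per-base read-end tracks using exact conditional rate
    tests against a randomized background. A synthetic-data module generates
    every pipeline input with planted ground truth so all stages can be
    exercised and calibrated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
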