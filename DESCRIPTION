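Package: cloneaudit
Title: Reliability Auditing of Arrayed RNAi Feeding Clone Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: In-silico quality control for arrayed RNAi feeding libraries
    built from genomic PCR amplicons, such as the Ahringer C. elegans
    library. Screens each clone's primer pair against a genome with a
    desk-scale in-silico PCR engine (nearest-neighbor melting temperatures,
    3'-end stability, seed-anchored binding-site discovery, amplicon
    enumeration), models band separation on a virtual 1% agarose gel,
    scores every clone on a 0-100 penalty ledger with green/yellow/red
    classification, remaps clones to the genes their amplicons actually
    silence, detects plate loading-error shifts, proposes replacement
    primer pairs for failing clones, and aggregates results into plate
    maps, category summaries and sequencing-validation cross-tabulations.
    Includes a seeded synthetic-data generator that emulates a small
    genome with paralog families and retired gene names plus a plated
    library with injected defects, so the whole pipeline is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
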