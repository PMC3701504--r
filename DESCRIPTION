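Package: armAnchor
Title: Scaffold Assignment and Misassembly Detection from Microdissected
    Chromosome-Arm Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns genome-assembly scaffolds to a laser-microdissected
    chromosome arm from the density of uniquely mapping short reads, and
    flags misassembled (hybrid) scaffolds from gaps in unique-read
    coverage. Implements the Bowtie-style uniqueness filter (report a
    read only if it has exactly one genomic location within a mismatch
    budget) with a pigeonhole seed-indexed mapper, per-scaffold hits/kb
    scoring, anchor- or region-calibrated density thresholds, windowed
    coverage profiles with large-gap detection and dense/sparse region
    segmentation, and a fully seeded synthetic-data generator that
    emulates the microdissection/WGA/sequencing experiment (arm
    enrichment, amplification duplicates, primer chimeras, off-target
    contamination, repeat-induced multimapping, laser-boundary taper and
    implanted hybrid scaffolds) so the whole pipeline is testable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
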