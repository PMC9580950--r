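Package: mirbench
Title: Synthetic Small RNA-Seq Simulation, Seed-Based Annotation, and Pipeline Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking small RNA-seq analysis pipelines. Generates
    synthetic FASTQ read sets with a configurable mixture of known miRNAs,
    novel miRNAs, known piRNAs, and altered decoy sequences, together with a
    machine-readable ground-truth table (class, locus, expression count,
    CIGAR). Implements the post-alignment annotation logic needed to resolve
    small-RNA identities: read-length triage into miRNA and piRNA tracks,
    Phred quality filtering, reverse-complement re-annotation against a local
    known-miRNA index, seed-based clustering of novel candidates with
    paralogue nomenclature, and count deduplication. Scores predictions
    against ground truth with four-class confusion tallies, accuracy, F1,
    and validation-style false-positive/false-negative percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    tibble,
    dplyr,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
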