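Package: eventcov
Title: Event-Based Depth-of-Coverage Calculation from SAM/BAM Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes sequencing depth of coverage from coordinate-sorted
    SAM/BAM files with the event-based (delta-encoding) algorithm: alignment
    blocks extracted from CIGAR strings place +1/-1 events at block
    boundaries, and a cumulative sum recovers per-base depth. The read
    stream can be split into an arbitrary number of partitions processed
    independently; genomic overlaps between consecutive partitions' partial
    coverage vectors are corrected by a tail-trim/head-add step, so results
    are identical for every partition count. Three output types are
    provided: per-base depth, equal-coverage blocks, and fixed-length
    window means. Includes a seeded synthetic-alignment generator and an
    independent brute-force pileup oracle for verification, plus a
    command-line interface with TSV/CSV/BED writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rsamtools,
    GenomicAlignments,
    IRanges,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    optparse,
    withr,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
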