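Package: concatemeR
Title: Multi-Contact Concatemer 3C Read Processing and Contact Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes long concatemer reads from chromosome conformation
    capture (3C) experiments sequenced on long-read platforms. Performs in
    silico restriction digestion of concatemer reads and reference genomes,
    expands the segments of each read into all pairwise chromatin contacts,
    emits mock Illumina-like paired-end records for scaffolders, filters and
    de-duplicates contact pairs, imputes haplotype phase to unphased segments
    from concordant phased segments on the same read, bins contacts into
    symmetric matrices with Knight-Ruiz balancing, and compares TAD partitions
    with the measure-of-concordance and reciprocal-overlap Jaccard metrics.
    Includes a seeded simulator that generates a diploid genome and
    ground-truth proximity-ligation concatemers so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
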