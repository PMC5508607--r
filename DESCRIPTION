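Package: alndiff
Title: Classification of Differences Between Two Closely Related Sequence Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and categorizes every difference between a reference
    sequence set and a closely related query sequence set (for example an
    assembly versus a finished genome, or two strains of the same species).
    Alignment fragments are obtained either from a built-in anchor-based
    aligner or from MUMmer-family tabular output, and the relative placement
    of neighbouring fragments is analysed to classify differences into a
    full taxonomy: simple insertions and deletions, interspersed and tandem
    duplications, collapsed repeats, substitutions, gaps of unknown bases,
    unaligned regions, translocations, relocations, reshufflings and
    inversions. Results are written as dual-coordinate GFF3 tracks suitable
    for genome browsers, per-type summaries, and per-base bedGraph
    aggregations across many genomes. A simulation engine generates random
    genomes with controlled modifications of every type, together with a
    machine-readable truth ledger for recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
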