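Package: circmine
Title: Detection and Characterisation of Exonic Circular RNAs from
    Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An annotation-anchored pipeline for identifying exonic
    circular RNAs (circRNAs) from paired-end RNA-seq reads via a
    back-splice junction sequence library, with mate-inside-the-circle
    verification, junctions-per-million (JPM) normalisation and abundance
    thresholds. Downstream analyses cover matched reference gene and
    feature sets, back-splice acceptor/donor positional profiles and
    exon/intron length statistics, polysome-fraction translation-candidate
    calling with circular open reading frame scanning, AGO-anchored miRNA
    seed-match sponge scoring, and NET-seq RNA polymerase II dwell-time
    comparisons with exon-scaled metagene profiles. A deterministic
    synthetic-data generator emulates the statistical structure of the
    source datasets so every stage is runnable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
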