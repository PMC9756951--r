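Package: scTRact
Title: Transcription-Regulator Activity and Target Inference from Single-Cell ATAC-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-cell transcription-regulator (TR) activity from
    scATAC-seq peak or bin count matrices by counting genomic-interval
    overlaps against a curated reference of TR ChIP-seq peak sets and
    motif-derived pseudo-peak sets, normalizing for reference size and
    per-cell accessible base pairs, and scaling scores through dataset
    centering, per-TR sigmoid transformation, and per-cell z-scoring.
    Imputes per-cell TR binding sites from each cell's best-matched
    reference dataset and scores target genes with an exponential
    distance-decay regulatory-potential model, supporting differential
    target detection between cell groups and construction of single-cell
    gene-regulatory networks. Includes tools to curate raw ChIP-seq peak
    sets and motif scan results into a searchable reference index, and
    seeded synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    data.table,
    jsonlite,
    optparse
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
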