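Package: sncforge
Title: Harmonised Small RNA Annotation Forging, Dual Quantification and
    Differential Expression for piRNA-Focused Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a harmonised small non-coding RNA annotation track by
    merging a piRNA database with a general sncRNA database (sequence
    collapsing, ungapped genome realignment, length and coding-overlap
    filtering, biotype re-classification, piRNA-cluster/genic region and
    transposable-element metadata), quantifies small RNA-seq libraries with
    two parallel strategies (genome alignment plus feature counting, and
    equivalence-class EM transcript abundance with bootstrap uncertainty),
    and analyses the resulting count matrices: CPM filtering, TMM/TMMwsp/RLE
    normalisation, exploratory summaries, voom/moderated-t differential
    expression with cross-method consensus, piRNA sequence signatures
    (1U/10A bias, ping-pong 5' overlap, length distributions, strand
    coverage) and complementarity-based target prediction. Seeded synthetic
    fixture generators with planted ground truth allow the whole pipeline to
    run and be tested without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    edgeR,
    limma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
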