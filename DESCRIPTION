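Package: circtk
Title: Exhaustive Detection, Annotation and Comparison of Circular RNAs
    from Chimeric Split Alignments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects circular RNAs from split-alignment chimeric junction
    tables (STAR chimeric.out.junction dialect) by selecting circular
    chimeric reads (CCRs), clustering them into back-splice junction
    candidates and filtering on read support and genomic size. Candidates
    are classified against an Ensembl-style gene annotation as exonic,
    sub-exonic (sense or antisense), intronic (donor-anchored with a
    bounded acceptor offset) or unannotated, and parent genes are
    assigned. Includes TMM-normalized expression aggregation across
    datasets and batches, Top-N circular transcriptome comparisons,
    cross-species orthologous circRNA detection by reciprocal best hits
    of junction-spanning sequences, and a fully seeded synthetic-data
    generator that plants circRNAs of every class with machine-readable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
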