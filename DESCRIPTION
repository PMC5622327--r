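Package: p53enhancer
Title: MPRA Quantification and Chromatin Accessibility Classification for
    p53-Bound Enhancers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the analysis of massively parallel reporter assay
    (MPRA) screens of p53-bound enhancer sequences and of chromatin
    accessibility changes at p53 binding sites during the DNA damage
    response. Provides MPRA oligonucleotide pool design (endogenous,
    motif-scrambled and random control variable regions, each linked to
    unique barcode tags), exact barcode counting from targeted RNA-seq
    reads, tag aggregation and a negative-binomial Wald test for
    differential reporter activity, a per-position per-base sequence
    activity contribution matrix, FPKM-based classification of binding
    sites into accessibility classes (constitutively accessible,
    constitutively inaccessible, pioneering, intermediate), transcription
    factor enrichment within pioneering sites with a label-shuffling
    permutation null, hypergeometric co-occurrence statistics, and a
    fully parameterised synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
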