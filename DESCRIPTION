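Package: pesca
Title: Paralleled Enhancer Single-Cell Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing paralleled enhancer
    single-cell assays (PESCA), in which a pooled library of candidate
    gene regulatory elements (GREs), each driving a barcoded reporter
    transcript, is read out by single-nucleus RNA sequencing to measure
    the cell-type specificity of every element at once. Covers selection
    of conserved, cell-type-specific GRE panels from ATAC-seq peak
    signal; design and validation of DNA barcode sets separated by a
    minimum edit distance; mismatch-tolerant deconvolution of viral
    barcodes from single-nucleus reads into UMI count matrices;
    pseudocounted fold-enrichment scores with barcode-triplet
    consistency and shuffle nulls; negative-binomial likelihood-ratio
    tests of cell-type enrichment with FDR control; binomial-thinning
    power analysis; and a synthetic-screen generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
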