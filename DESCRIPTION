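Package: stheart
Title: Spatially Resolved Transcriptomics of Cardiac Tissue Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale implementation of a spatial transcriptomics (ST)
    workflow for adult human heart biopsies: design of a spatially barcoded
    microarray (1,007 features, 18-nt spatial barcodes, WSNNWSNNV degenerate
    molecular identifiers), simulation of ground-truth molecule ledgers and
    paired-end reads over region-structured tissue sections, the read-level
    processing chain (homopolymer and quality trimming, length and rRNA
    contaminant filters, k-mer gene assignment, exact barcode demultiplexing,
    UMI duplicate collapse) down to a feature-by-gene molecule count matrix,
    and the comparative statistics layer (median-of-ratios size factors,
    pseudocount log transforms, pairwise Pearson correlation, PCA on top
    expressed genes, thresholded differential expression, sequencing
    saturation curves). Its headline statistic contrasts per-expressing-
    feature signal (spatial) with per-all-feature signal (bulk-treated) to
    quantify the sensitivity gain of spatial resolution for lowly expressed
    fetal marker genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    data.table,
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    Rtsne,
    cluster,
    igraph,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
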