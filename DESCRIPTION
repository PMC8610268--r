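Package: numtsieve
Title: Machine-Learning Separation of Mitochondrial Reads from Nuclear
    Mitochondrial Segments (NUMTs)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies paired-end sequencing reads that align to the
    mitochondrial genome as genuine mitochondrial DNA (mtDNA) or as
    nuclear-encoded mitochondrial segments (NUMTs), using a random forest
    over alignment-derived features: mitochondrial and nuclear edit
    distances, a linkage-disequilibrium co-occurrence score of the variants
    carried by the read pair, and the fractional overlap of the fragment
    with known NUMT regions. Includes a haploid LD r-squared table builder
    from mitochondrial haplotype panels, an MD-tag mismatch caller, a
    pileup heteroplasmy estimator, mtDNA copy-number estimation,
    benchmark-comparison statistics for heteroplasmy call sets, and a
    labelled paired-end read simulator (mtDNA, NUMT and rho-zero
    libraries) for training and validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    data.table,
    jsonlite,
    randomForest,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
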