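Package: ecRegulome
Title: Differential Chromatin Activation and Contact-Map Reassembly for
    Hybrid ecDNA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of the regulatory landscape of human-papillomavirus
    hybrid extrachromosomal DNA (ecDNA). Implements a differential
    chromatin-activation statistic designed for low-replicate ChIP-seq
    designs (percentile-restricted RLE size factors, a loess-modelled
    standard-deviation-versus-mean trend, approximate z-scores and an
    empirical-Bayes local false discovery rate), intersection of
    differential H3K27ac peaks with promoter (H3K4me3) and enhancer
    (H3K4me1) mark regions, and reconstruction of binned Hi-C contact
    maps along ordered, oriented circular ecDNA structures followed by
    ICE matrix balancing. Ships seeded synthetic-data generators with
    recorded ground truth so that every stage of the pipeline can be
    exercised and benchmarked without access to protected sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    GenomeInfoDb,
    methods,
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'diff-lfdr.R'
    'diff-normalize.R'
    'diff-trend.R'
    'diff-call.R'
    'hic-assemble.R'
    'hic-compare.R'
    'hic-ice.R'
    'io-bed.R'
    'io-cycles.R'
    'io-matrix.R'
    'io-results.R'
    'methods.R'
    'peak-quant.R'
    'simulate.R'
    'pipeline.R'
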