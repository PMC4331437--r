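Package: retroMosaic
Title: Somatic Retroelement Insertion Analysis from Junction Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection and statistical analysis of somatic L1 and Alu
    retroelement insertions from suppression-PCR junction libraries across
    multiple tissues of one individual. Provides a sequence-level simulator of
    restriction-digest junction libraries (toy genome, planted germline and
    tissue-specific somatic insertions, paired FASTQ plus truth BED), a
    seed-and-extend junction caller with single-base coordinate resolution,
    cross-tissue classification of calls into reference, germline and somatic
    insertions, strand-aware gene and promoter annotation, and the full
    statistical battery: exact conditional two-sample Poisson rate tests,
    Monte-Carlo genomic-distribution null tests, a chi-square overdispersion
    test on grouped proportions, and exact binomial orientation-bias tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    knitr
Config/testthat/edition: 3
biocViews: Software, Sequencing, Retrotransposition, StructuralVariation,
    StatisticalMethod
RoxygenNote: 7.3.3
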