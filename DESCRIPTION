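Package: psgtools
Title: Probabilistic Splice Graph Models for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantification of alternative pre-mRNA processing from RNA-Seq
    data with probabilistic splice graphs (PSGs): compact weighted DAG models
    in which every isoform is a path and edge weights are conditional
    probabilities of processing events.  Provides graph construction from
    transcript annotations (line, order-h exon and unfactorized flavors),
    dynamic-programming derived quantities (vertex inclusion probabilities,
    expected prefix/suffix/transcript lengths), a generative read model with
    poly(A) tail handling, MAP/ML edge-weight estimation by EM, a
    junction-read baseline estimator, identifiability certification from
    unique-read conditions, likelihood-ratio tests for differential
    processing between two samples with Benjamini-Hochberg FDR control, and a
    model-faithful fragment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    rtracklayer,
    Rsamtools,
    BiocGenerics,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
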