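Package: promdiverge
Title: Promoter Motif Divergence, Parsimony Phylogenetics and Microglial
    Activation Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying clade-restricted transcription
    factor binding sites in gene promoters and their downstream expression
    consequences. Provides position-weight-matrix promoter scanning with
    differential motif enrichment (one-sided Fisher test with
    Benjamini-Hochberg correction), maximum-parsimony phylogenetics on
    promoter alignments (Fitch counting, tree-bisection-reconnection
    search, bootstrap support, consistency and retention indices),
    DerSimonian-Laird random-effects meta-analysis of per-dataset
    differential expression, single-cell gene-set scoring and pseudobulk
    differential expression, signed-hybrid co-expression networks with
    topological-overlap module detection, and a multi-stage promoter
    occupancy biomarker screen. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    metafor,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
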