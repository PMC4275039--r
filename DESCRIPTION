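Package: trnsel
Title: Selection on Coding and Cis-Regulatory Sequences in Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the topology of a transcriptional
    regulatory network (TRN) shapes the strength of natural selection on
    coding and putative cis-regulatory sequences. Implements a modified
    McDonald-Kreitman framework: per-gene polymorphism and divergence
    counts for synonymous, replacement and upstream regulatory sites are
    tabulated from gene models, genome sequence and labelled variant
    sites, and population-scaled selection coefficients (gamma) are
    estimated per gene with a Poisson random-effects model and
    empirical-Bayes shrinkage. Companion network tools build the directed
    TF-target graph, classify hub genes, compute betweenness and
    eigenvector centrality, and fit a discrete power law to the
    connectedness tail with a bootstrap goodness-of-fit test. A
    synthetic-data generator with a full ground-truth ledger (scale-free
    degree sequences, truncated-normal gamma mixtures, Poisson count
    tables, and small annotated genomes) makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    igraph,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    jsonlite,
    withr,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
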