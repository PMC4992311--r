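Package: regulonscan
Title: Operator-Box Discovery and Label-Free Proteomics for Bacterial
    Regulon Definition
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for defining the regulon of a bacterial transcription
    factor that binds a palindromic operator box. Builds degenerate IUPAC
    consensus motifs from aligned operator sites, detects perfect and
    imperfect inverted repeats in promoter regions, scans annotated
    genomes for operator boxes under positional constraints relative to
    translational starts, refines motifs with a one-occurrence-per-sequence
    expectation-maximisation algorithm, and implements a label-free
    quantitative proteomics workflow (identification and peak filtering,
    peptide selection, imputation, median-ratio run normalisation, protein
    roll-up, Kruskal-Wallis peak-count and one-way ANOVA testing, signed
    fold changes). Ships simulators that generate planted-motif genomes
    and peptide-intensity datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
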