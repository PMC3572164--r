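Package: asymma
Title: Two-Color Microarray Analysis of Asymmetrically Inherited Maternal Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for custom two-color expression microarrays
    profiling maternal transcript pools in early invariant-cleavage embryos.
    Covers probe-to-contig mapping with cross-hybridization filtering and a
    second-round EST rescue, normexp background correction, print-tip loess
    and A-quantile normalization, median-polish summarization of multi-probe
    targets, empirical-Bayes moderated statistics with Benjamini-Yekutieli
    multiple-testing correction, negative-control (antisense probe) expression
    thresholding, maternal/zygotic classification, cross-experiment asymmetry
    cataloguing with temporal grouping, and Fisher's exact GO-term
    overrepresentation analysis. Includes a probe-level synthetic data
    generator with planted ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    limma,
    Biostrings,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
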