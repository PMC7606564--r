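Package: nadscape
Title: Analysis of NAD CaptureSeq 5'-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of NAD captureSeq experiments, in which
    ADPRC-treated (+ADPRC, "S") libraries are compared against untreated
    (-ADPRC, "N") background controls to identify NAD-capped RNA species.
    Provides enrichment calling on 5'-UTR-window count matrices with a
    negative-binomial Wald test, TPM-based NAD-modification-ratio
    estimation, transcription-start-site cluster detection with a weighted
    linear-by-linear trend test for alternative TSS usage, sharp-A TSS
    calling and promoter position-frequency matrices (YAAG core motif),
    per-read 5'/3' geometry and full-length-fraction analysis, decapping
    enzyme hierarchy inference across knockout-strain lattices, and a
    fully parameterised synthetic-data generator with planted ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite
Config/testthat/edition: 3
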