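Package: dhsreg
Title: Integrated Open-Chromatin and Expression Analysis of BMP4 Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for dissecting phenotype-specific responses to
    BMP4 in breast cancer cell lines from paired RNA-seq and DNase-seq data.
    Implements threshold-based differential expression calling after
    median-of-ratios normalization, DNase hypersensitive site (DHS)
    filtering, merging and genomic annotation, a differential
    hypersensitivity change score (deltaDHS), expression-weighted
    transcription start site openness classification, position weight matrix
    construction from weighted positional count matrices with exact
    score-distribution threshold calibration, background-normalized
    transcription-factor binding-site enrichment in promoter DHSs,
    SMAD-binding-element co-localization testing, and median-split log-rank
    survival screening. Ships a synthetic-data module that generates all
    inputs with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    survival,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
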