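Package: scostress
Title: Oxidative-Stress Transcriptome Pipeline for Streptomyces Two-Component
    System Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-usable implementation of a bacterial RNA-Seq analysis
    workflow for two-component-system regulons in high-GC actinomycetes:
    paired-read fragment assembly with a 1-kb insert limit, pseudocount
    RPKM quantification per CDS, MA-statistic differential-transcription
    calling with a self-calibrated M-value cutoff (2.58 x STDEV),
    response-regulator operator-site scanning by ungapped percent
    identity with sequence-logo information content, and qRT-PCR
    crossing-point analysis with propagated uncertainty.  Ships a
    synthetic-data generator with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
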