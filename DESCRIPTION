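Package: esttf
Title: Transcription Factor Identification and Expression Specificity from EST Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription factors (TFs) in expressed sequence tag
    (EST) collections by six-frame translation, cd-hit-style greedy identity
    clustering, profile hidden Markov model domain scanning with Gumbel
    E-value calibration, and DNA-binding-domain family rules; classifies each
    TF as developmental-stage-specific, tissue-specific, unspecific or unclear
    from EST-library annotations; validates putative specific TFs against
    matched alignment hits and recovers annotations from clustered-away
    sequences; and tabulates family-by-category counts, seven-set Venn region
    counts, cross-database redundancy and genome-percentage summaries. A
    synthetic-corpus generator with planted ground truth makes every pipeline
    stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
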