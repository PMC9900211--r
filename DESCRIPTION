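Package: regindel
Title: Tissue-Specific Prioritization of Regulatory Non-Coding Small Indels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific labeled sets of non-coding small
    insertions and deletions (nc-sindels) from eQTL summary statistics,
    featurizes each variant with generic functional annotations plus
    epigenomic profiles predicted from fixed-length reference and
    alternative sequence windows, trains per-tissue gradient-boosted
    classifiers, and evaluates them with within-tissue cross-validation,
    cross-tissue and independent-study transfer protocols. Also quantifies
    enrichment of true and predicted regulatory indels in
    promoter-capture Hi-C anchors and ChIP-seq peak regions with
    GC-matched negative sampling, odds ratios and one-sided Fisher's
    exact tests. Includes a synthetic-data generator with planted signal
    so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
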