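Package: tempoNMF
Title: Temporal Behavior Decomposition of Time-Series RNA-Seq by Non-Negative
    Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes dense time-series bulk RNA-seq expression matrices into
    a small number of non-negative temporal "behaviors" (metagenes) using
    multiplicative-update non-negative matrix factorization, with rank
    selection by the local minimum of successive-approximation RMSE and a
    restart-based robustness protocol. Includes median-of-ratios library-size
    normalization, replicate outlier detection by z-scores on principal
    component scores, dominant-behavior assignment and display ordering,
    per-behavior gene-list extraction, correlation-based clustering of
    transcription factors, and enrichment of TF-binding peaks in proximal and
    distal windows around transcription start sites with a one-sided exact
    test. A synthetic-data generator with pulsatile ground-truth behaviors,
    sparse non-negative gene weights, multiplicative replicate noise, planted
    outlier replicates and toy peak/TSS geometry makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
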