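Package: k9diff
Title: Differential H3K9me3 Heterochromatin Domain Analysis from Binned ChIP-Seq Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genomic domains that gain, lose or retain the
    heterochromatin mark H3K9me3 between conditions, starting from binned
    (200 bp) ChIP-seq coverage tracks. Provides cross-sample quantile
    normalization, input subtraction ("noise reduction"), a two-cutoff broad
    peak caller with weak-segment linking, construction of a clustered union
    peak set, k-means classification of peak-centred signal matrices into
    gain/loss/common classes, and a shuffle-based observed/expected statistic
    for repeat-element and promoter enrichment with a one-sample t-test and an
    optional calibrated empirical permutation p-value. A synthetic-data
    generator plants heterochromatin domains and repeat-class enrichment with
    a full truth table, so every stage of the pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    withr
Config/testthat/edition: 3
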