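Package: mirnaome
Title: Small RNA Read Classification and miRNAome Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genome-mapped small-RNA reads against annotated
    miRNA hairpins into mature miRNAs, six isomiR classes (templated and
    non-templated 3'/5' variants and seed/non-seed SNP variants), miRNA
    offset RNAs (moRs) and loop RNAs (loRs). Derives arm dominance,
    arm co-expression and arm switching across libraries, performs
    median-of-ratios count normalization and Pearson/average-linkage
    expression clustering, detects genomic miRNA clusters within a
    configurable window, and screens novel hairpin candidates with a
    pluggable folding backend. Ships a synthetic-data generator that
    plants hairpins in a toy genome and emits stage-labelled read
    libraries with ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
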