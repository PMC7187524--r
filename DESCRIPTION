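Package: irrscan
Title: Catalog-Free Discovery of Short Tandem Repeat Expansions from
    Short-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large short tandem repeat (STR) expansions in
    whole-genome short-read sequencing data without a predefined repeat
    catalog. Reads that lie entirely within a repeat (in-repeat reads,
    IRRs) are recognized by a periodicity score and a base-quality
    weighted purity score, attributed to a canonical repeat motif, and
    summarized into per-sample genome-wide STR profiles of anchored and
    paired IRR counts. Profiles are merged across a cohort and expanded
    loci or motifs are prioritized by a one-sided Wilcoxon rank-sum
    case-control test or by a bootstrap 95 percent quantile outlier
    z-score. A paired-end read simulator with emulated alignment makes
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
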