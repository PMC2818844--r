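Package: chromtile
Title: Promoter Chromatin-State Analysis for ChIP-chip Tiling Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of promoter tiling-array ChIP-chip experiments
    profiling histone methylation (H3K4me3, H3K27me3) in early embryonic
    lineages. Implements sliding-window peak detection with a
    randomization-based false discovery rate, MaxTen promoter scoring,
    replicate-concordant enrichment calls and bivalency classification,
    TSS-anchored metagene profiles, and cross-lineage overlap and
    asymmetry statistics, together with a synthetic data generator that
    emulates the promoter array design with planted per-lineage
    enrichment states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
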