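Package: primatecons
Title: Cross-Species Conservation and Co-Binding Analysis of Transcription
    Factor ChIP-Seq Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of transcription-factor binding
    maps across related species, modelled on multi-primate CTCF/YY1 ChIP-seq
    studies. Binding events are projected between genomes over orthology
    alignment blocks and classified into six cross-species conservation
    classes; CTCF/YY1 peak sets are partitioned into factor-only and co-bound
    classes and related to genomic features and transcript expression; repeat
    family enrichment is tested with a binomial model calibrated against
    randomized peak placements; and motif-word statistics (normalized
    occurrences and normWord log-ratios) detect species- or clade-specific
    expansions of binding words. A seeded synthetic-world generator emulates
    the joint structure of these data so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
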