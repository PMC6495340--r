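Package: jboxr
Title: Knockout Time-Course Regulon Inference and J-Box Promoter Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers sigma-factor regulons from knockout time-course RNA-seq of
    developing cyanobacterial hormogonia and dissects their promoters. Computes
    log2 ratio-to-baseline expression profiles, flags differential expression
    with moderated F-tests, assigns genes to sigJ/sigC/sigF regulons by ranking
    Euclidean (L2) norms of mutant-versus-wild-type trajectories, clusters
    profiles by UPGMA, discovers promoter motifs in expression clusters with a
    ZOOPS EM algorithm, builds a GGG-anchored consensus promoter (the J-Box,
    an extended -10 element), scans genomes for J-Boxes with a parameterized
    rule, and quantifies transcripts by the 2^-ddCt method. Ships a synthetic
    data generator that plants the full regulatory cascade (counts, genomes
    with planted promoter sites, qPCR tables) so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    limma,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
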