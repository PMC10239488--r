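Package: retroscape
Title: Transposable Element Divergence Landscapes and Insertion Density
    Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of RepeatMasker-style repeat annotation for
    comparative genomics of transposable elements (TEs). Parses '.out'
    annotation tables and '.align' alignment files, computes Kimura
    2-parameter divergence between TE copies and their consensus
    sequences, merges annotation fragments into insertions, and builds
    divergence landscapes and per-class genome-content summaries.
    Implements the density-of-insertion (DI) statistic for young non-LTR
    retrotransposons, lifespan-ratio pairing of species with an exact
    Wilcoxon signed-rank test, windowed insertion and gene-feature
    densities with Spearman correlations and gene-rich/gene-poor
    contrasts, and a screen for LINE open reading frames carrying intact
    reverse-transcriptase and endonuclease domains. A ground-truthed
    simulator generates genomes, annotations, gene models, and
    multi-species cohorts so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
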