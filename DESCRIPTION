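Package: recombevol
Title: Comparative Analysis of Global Recombination Rate Evolution Across
    Plant Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for relating global meiotic recombination rate to genome
    architecture, codon composition, and rates of molecular evolution across
    species. Estimates recombination rates from genetic linkage maps with
    marker-density correction (Chakravarti's method 4), derives
    genome-architecture traits (euchromatin-corrected rates, genome size
    without LTR retrotransposons, gene density, compactness), computes
    phylogenetic independent contrasts and their correlations, Blomberg's K
    with permutation tests, Cohen's correlation power analysis, fixed-effects
    meta-analysis of correlations, Wright's effective number of codons and GC
    content at fourfold-degenerate third positions, and calibrated screening
    of per-gene trait-dN/dS coevolution output. Includes generators for
    synthetic phylogenies, Brownian-motion traits, finite-marker linkage
    maps, codon alignments, and coevolution tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
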