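Package: dietlink
Title: Molecular Diet Analysis from Metabarcoded Predator Gut Contents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for DNA metabarcoding diet analysis of
    invertebrate predators: simulation of multiplexed CO1 amplicon reads
    with known gut-content ground truth, demultiplexing by multiplex
    identifier (MID) tags, length filtering, haplotype collapsing, greedy
    centroid MOTU clustering across a similarity-threshold grid with
    data-driven threshold selection, taxonomic assignment against a
    barcode reference, presence/absence diet matrices, niche breadth
    (Levins) and overlap (Pianka) statistics with Monte-Carlo null
    models, a proportional-abundance prey-choice null with 95 percent
    confidence limits and preference classification, and community
    summaries (Bray-Curtis/NMDS, PERMANOVA, gradient vector fitting,
    species accumulation, Chao2 richness, rarefaction).
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
    vegan,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
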