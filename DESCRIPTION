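Package: genopair
Title: Comparative Statistics and Fragment-Recruitment Discrimination for Prokaryote Genome Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-based comparative genomics for pairs of prokaryote
    genomes: seeded local alignment of genes and short fragments, directional
    and reciprocal best hits, average nucleotide identity (ANI), two-way
    average amino acid identity (AAI), percent shared genes, shared and
    unique homolog inventories with COG-category summaries, and a
    fragment-recruitment procedure that calibrates an identity threshold for
    discriminating reads between two related genomes. Includes a genome-pair
    simulator (substitutions with transition/transversion bias, codon-aware
    indels, gene loss, read mixtures) that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
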