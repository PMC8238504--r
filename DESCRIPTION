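Package: flavimine
Title: Mining Flavinylation-Associated Gene Clusters in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for discovering extracytosolic
    protein flavinylation systems in annotated prokaryotic genomes. Detects
    anchor genes encoding ApbE, FMN-binding, DUF3570 or DUF2271 domains,
    collects their five-gene neighborhoods, applies a signal-peptide/
    lipoprotein localization filter, assigns the resulting gene clusters to
    ten named extracytosolic electron-transfer systems by key-gene rules,
    scans protein sequences for the [S/T]GA[S/T] flavinylation motif,
    computes sequence-logo information content, detects multi-flavinylated
    proteins and orphan ApbE genomes, and summarizes system presence per
    genome, genus and phylum. Ships a synthetic annotated-genome generator
    with a ground-truth ledger so every pipeline stage is testable without
    external downloads.
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
    methods,
    purrr,
    stats,
    tools,
    utils,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
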