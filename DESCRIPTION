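Package: mirquest
Title: Homology-Based Discovery and Validation of Conserved Plant miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for discovering conserved plant
    microRNAs in transcript collections (ESTs and transcriptome shotgun
    assemblies): ungapped mismatch-limited homology scanning against a
    reference set of mature miRNAs, coding-sequence filtering, sliding-window
    precursor extraction with hairpin validation (MFE, AMFE, MFEI, AU/GC
    composition, star-strand duplex checks), psRNATarget-style miRNA:mRNA
    expectation scoring with cleavage/translation classification, and
    2^-deltaCt relative-expression analysis of stem-loop RT-qPCR data with
    miRNA/target inverse-expression flagging. Includes seeded synthetic-data
    generators (planted hairpins, decoys, target sites, Ct tables) so every
    stage can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
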