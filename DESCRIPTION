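Package: pepcover
Title: Family-Unique Tryptic Peptide Selection for Targeted Metaproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects minimal panels of tryptic peptides that are unique to
    CAZyme (glycoside hydrolase) families across a community of
    metagenome-assembled genome (MAG) proteomes. Applies a multi-tool
    consensus rule to dbCAN2-style annotations, builds target and background
    peptidomes by in silico tryptic digestion (100%-identity deduplication,
    N-terminal trimming and empirical peptide filters on targets), computes
    family-unique peptides, approximates the minimum peptide set cover
    greedily, and summarises the enzymatic (EC) and phylum-level groupings
    the selected peptides resolve. Includes a parameterised synthetic
    MAG-community generator with planted conserved peptides for end-to-end
    validation.
License: MIT
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
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
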