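Package: lratlas
Title: Cross-Tissue Ligand-Receptor Co-Expression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for screening ligand-receptor gene pairs across a
    pair of tissues from bulk RNA-seq expression: quantify transcripts per
    million (TPM) from read counts, average replicates, identify expressed
    receptor genes in a receiver tissue, pair them with ligand(-related)
    genes expressed by a sender tissue via a FANTOM5-style interaction
    database, classify pairs into dual-expression quadrants, inventory
    autocrine ligands and orphan receptors, and test gene sets for
    hypergeometric overrepresentation. Includes a synthetic-data generator
    with planted high/high pairs for end-to-end validation, tidy
    (tibble-based) interfaces throughout, and ggplot2 figures mirroring
    the atlas-style bar charts and quadrant scatters used in
    embryo-maternal crosstalk studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
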