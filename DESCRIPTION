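Package: arrayevo
Title: Architecture and Evolution of Bacterial Chemosensory Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how gamma-proteobacterial chemosensory systems
    evolved control of the flagellar motor. Collapses cryo-electron tomography
    density volumes into 1D profiles along the membrane normal and measures
    inter-layer distances with expanded (k = 2) uncertainties; estimates the
    hexagonal receptor-lattice spacing from top-view images; classifies F7
    chemosensory gene clusters into five evolutionary stages by edit distance
    to arrangement templates; clusters proteins into homolog families by
    single linkage over pairwise-score thresholds; scans receptors for the
    C-terminal pentapeptide CheR-tether motif; and locates residues that are
    conserved within CheY groups but differ between the ancestral F6 group
    and the flagellar stage-3/4/5 groups, including charge reversals. A
    synthetic-data module generates membrane/layer phantom volumes, hexagonal
    lattice images, staged gene clusters, group-structured alignments and
    receptor sets with machine-readable ground truth, so every analysis is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    igraph,
    generics,
    withr,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
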