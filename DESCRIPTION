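Package: pandiverge
Title: Pan-Genome Divergence Analysis for Bacterial Clades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for studying divergence within a
    bacterial genus: marker-gene (16S rRNA) filtering, Tamura-Nei (TN93)
    distances and substitution-saturation assessment, neighbor-joining trees
    with outgroup rooting, ANIb-style average nucleotide identity and the 95%
    species-delineation call, greedy ortholog clustering into core, accessory
    and strain-specific gene families, pan-genome rarefaction with Heaps'-law
    (power-law) and exponential core-genome model fitting, Wagner-parsimony
    gene gain/loss reconstruction with per-branch turnover rates, and
    composition-vector (K-tuple) alignment-free phylogenomics. Includes a
    simulator that generates clades of genomes with known trees, gene
    gain/loss histories and substitution parameters so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
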