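Package: panreplicon
Title: Pan-Genome, Repeat and Divergence Analysis of Multipartite Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of bacterial genomes that are split across
    several replicons (a chromosome, megaplasmids and accessory plasmids), as
    found in Ensifer (Sinorhizobium) meliloti and other rhizobia. Provides
    gene-family clustering by Markov clustering of protein-similarity scores,
    core/pan-genome curves and per-replicon core sets, discovery of repeat
    element families from genomic self-matches with profile-based genome
    scanning, transposon-associated locus classification from functional
    labels, detection of inter-replicon gene movement and large synteny-based
    translocations, TN93 distances with Mantel permutation tests between
    replicon distance matrices, and a seeded synthetic-genome generator with
    machine-readable truth tables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
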