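Package: ctcoupler
Title: Coupling Between Chromosome Territory Organization and
    Transcriptional Activity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the coupling between the three-dimensional
    arrangement of chromosome territories in the interphase nucleus and
    the transcriptional output of the genome.  Builds inter-chromosome
    physical distance (IPD), activity distance (IAD) and basepair-length
    difference (IBD) matrices, correlates them under a row/column
    permutation null with a permutation false discovery rate, implements
    the network-coupling energy function H relating chromosome adjacency
    to transcription-factor-network activity (with randomization
    trajectories, optimality deviates and a length-scale scan), and
    extracts minimum interface distances between painted chromosome
    territories from two-channel confocal z-stacks.  A synthetic-data
    module generates nuclei, probe-level expression tables, network
    catalogs and phantom image stacks with known ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    pracma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
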