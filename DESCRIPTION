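Package: dicerscape
Title: Domain-Architecture Classification and Evolution of Fungal Dicer Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for clade-wide surveys of fungal Dicer (Dcr)
    proteins. Parses profile-HMM domain hit tables (HMMER domtblout dialect),
    applies a rule-based Dicer gate (tandem RNase III plus at least one
    RNA-binding domain) and a six-category domain-architecture classifier,
    extracts canonical and inferred fungal PAZ regions, builds thresholded
    sequence- and structure-similarity networks with connected-component
    clustering, fits a two-state equal-rates Mk model with marginal ancestral
    reconstruction of PAZ presence, computes structure-derived molecular-ruler
    distances from PDB models, and evaluates profile-HMM sensitivity and
    precision. Includes a seed-deterministic synthetic-data generator that
    plants known architectures, clusters, characters and structures so every
    stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
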