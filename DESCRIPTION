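Package: unbio
Title: Biochemical Space, UnBiological Scores and Low-Potency Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how far a small molecule lies outside the
    chemical space occupied by core metabolism, and for relating that
    distance to non-specific toxicity. Provides a 2-D molecular graph model
    with SMILES and SDF input, canonicalization, substructure matching and
    maximum common subgraph search; exhaustive enumeration of valence-legal
    chemical space over a configurable element set with stability filters;
    fragment pools built by iterated maximum-common-subgraph closure; the
    UnBiological score Ub_N (the largest connected region of a molecule
    containing no N-atom fragment of a metabolite reference set) together
    with a brute-force oracle; chemical-space coverage statistics; and a
    statistical layer for rank correlations of Ub with log half-effect
    concentrations, potency-band analyses, hit-rate curves and EC50
    estimation from growth-inhibition data. A seeded synthetic-data
    generator makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    igraph,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    ChemmineOB,
    jsonlite,
    optparse,
    readr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
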