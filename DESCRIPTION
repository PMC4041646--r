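Package: dsmda
Title: Simulation and Comparison of Direct-Sequencing and Whole-Genome-Amplified Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale tools for comparing direct sequencing (DS) of
    minimal-input shotgun libraries against multiple displacement
    amplification (MDA). Simulates DS-like reads with near-uniform genome
    coverage and MDA-like reads with priming-site amplification bias,
    chimeras, reagent-borne contaminants and template-free hexamer
    concatemers; provides read quality control (quality trimming, 3'
    Y-adaptor detection, low-complexity filtering), word-hash read mapping
    with per-base coverage tracks, two-sample Cramer-von Mises coverage
    comparison with permutation p-values, hexamer-composition attribution of
    unassigned reads (gamma fits, bootstrapped hierarchical clustering,
    correspondence analysis), greedy identity clustering of duplicated
    reads, and a minimal-library budgeting calculator built on qPCR
    standard-curve quantification and picotiterplate bead capacities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
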