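Package: repkit
Title: Hierarchical T Cell Receptor Repertoire Analysis
Version: 0.1.0
Authors@R: person("repkit", "developers", role = c("aut", "cre"),
    email = "repkit@example.org")
Description: Scriptable analysis engine for T cell receptor (TCR) repertoire
    sequencing data organised as a three-tier hierarchy: single-sample
    descriptive statistics (V/J segment usage, CDR3 spectratype, clonotype
    frequency distributions), pairwise comparisons (overlapping and private
    clonotype frequencies with coefficient of determination, convergent
    recombination analysis), and multi-sample group analyses (clonal space
    homeostasis with chi-square comparison, longitudinal clonotype tracking,
    similarity matrices with hierarchical clustering, diversity indices with
    rarefaction, and Wilcoxon group comparison). Samples are grouped through a
    delimited experiment design file so cohorts can be regrouped by any
    combination of variables. Reads MiXCR exportClones and AIRR Rearrangement
    clonotype tables, and ships a seeded synthetic-repertoire generator with
    controlled clonal expansion, V/J usage bias, CDR3 length spectra, sequence
    convergence and longitudinal dynamics, so every statistic is testable
    without external data. A command-line interface binds design-file grouping
    to all analyses with deterministic outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
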