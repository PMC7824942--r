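Package: tcrsimnet
Title: TCR Repertoire Similarity, Sharing Networks and CDR3 Motif Analysis
Version: 0.1.0
Authors@R:
    person("CSF Immunology", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing single-cell T cell receptor (TCR)
    repertoires from cerebrospinal fluid and other compartments. Reads 10x
    Cell Ranger VDJ contig annotations and AIRR Rearrangement tables, calls
    paired-chain clonotypes with unambiguity and clonal-expansion filters,
    scores all clonotype pairs with a length-normalised Levenshtein
    similarity (L-sim), extracts similarity clusters above a threshold,
    builds sample-organised TCR sharing networks with diagnosis-group
    sharing counts, enumerates CDR3beta motifs by sliding window with
    conserved-end trimming, and looks motifs up in a McPAS-TCR-format
    specificity database. Includes a synthetic repertoire generator with
    planted clones, similarity clusters and motifs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    igraph,
    jsonlite,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
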