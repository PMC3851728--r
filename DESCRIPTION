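Package: cladexpr
Title: Parsimony Cladistics of Gene Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic parsimony profiling of bulk gene-expression cohorts.
    Expression values of disease specimens are polarized against the empirical
    normal range (the minimum and maximum over healthy specimens) into binary
    derived characters, most-parsimonious cladograms are inferred under Wagner
    or Camin-Sokal criteria with an all-ancestral hypothetical root taxon,
    per-node synapomorphy gene lists are extracted by ancestral-state
    reconstruction, and congruence between cladogram clades and clinical
    phenotype labels is quantified. Includes a GEO series-matrix and TSV
    reader, PHYLIP MIX-compatible character output, hypergeometric gene-set
    over-representation of nodal gene lists, and a synthetic cohort generator
    with planted subtypes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
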