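Package: phylocurate
Title: Phylogenomic Supermatrix Curation and Congruence Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for curating phylogenomic amino-acid supermatrices and
    diagnosing congruence among phylogenetic analyses. Implements
    taxon-occupancy filtering of orthogroups, alignment end trimming,
    removal of rate-tail genes ranked by mean pairwise p-distance, a
    simulation-based test of amino-acid compositional homogeneity with a
    chi-square statistic and a neighbour-joining guide tree, Dayhoff
    6-state recoding, concatenation with partition bookkeeping, and
    outgroup-restricted subsetting. Tree-side utilities cover bipartition
    extraction, Robinson-Foulds distances, split-support congruence tables
    across analyses, posterior bipartition frequencies, the between-chain
    maxdiff convergence diagnostic, and rogue-terminal pruning from tree
    lists. A synthetic-data module simulates species trees, discordant
    gene trees, and alignments under a frequency-driven replacement model
    with controlled rate and compositional heterogeneity and patterned
    missingness, including a fixture shaped like a 74-taxon, 1059-gene
    gastropod transcriptome dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
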