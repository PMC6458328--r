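# phylocurate

Curation of phylogenomic amino-acid supermatrices and congruence
diagnostics for the trees inferred from them.

Deep splits — the relationships among the major gastropod lineages and
their mollusc outgroups are the motivating case — are where systematic
error thrives: extreme gene rates, amino-acid compositional
heterogeneity among lineages, gene-tree discordance and patchy taxon
occupancy can each produce confident but wrong trees. The standard
defence is to build a *family* of matrices from one set of orthologous
gene alignments and require congruence across matrices and methods:

* **matrix 1** — all genes at ≥ 50% taxon occupancy
  (`slice_by_occupancy`, threshold `⌈f·n_taxa⌉`);
* **matrix 2** — matrix 1 minus the 20% slowest and 20% fastest genes,
  ranked by mean pairwise p-distance (`gene_rate`,
  `remove_rate_tails`);
* **matrix 3** — the compositionally homogeneous subset of matrix 1
  (`composition_homogeneity_test`, `filter_homogeneous`);
* **matrix 4** — the ≥ 70% occupancy subset;
* Dayhoff 6-state recodings (`dayhoff_recode`) and
  outgroup-restricted variants (`subset_outgroups`) of the above.

The compositional test is simulation-based: the observed
taxon-by-residue X² statistic is compared with replicates evolved on a
neighbour-joining guide tree under a frequency-driven (equal-input)
replacement model with the gene's pooled frequencies, replicates
inheriting the gene's gap pattern; the Monte-Carlo p-value is
`(n_ge + 1)/(n_sims + 1)` and genes with `p < 0.1` are flagged.

Tree-side utilities parse Newick with support normalization, extract
canonical bipartitions, compute Robinson–Foulds distances, build
split-support congruence tables across analyses (absent splits marked
`NA`), compute posterior bipartition frequencies and the between-chain
**maxdiff** convergence diagnostic, and prune rogue terminals from tree
lists — the construction where two otherwise identical chains that
disagree only in one terminal's placement show `maxdiff = 1` until the
rogue is removed.

A synthetic-data module (`simulate_species_tree`,
`simulate_gene_trees`, `simulate_alignment`,
`apply_compositional_shift`, `apply_missingness`,
`make_gastropod_fixture`) generates datasets with controlled rate
heterogeneity, compositional shifts, NNI gene-tree discordance and
patterned missingness, including a fully reproducible fixture with the
dimensions of a 74-taxon, 1059-gene gastropod transcriptome study.

## Worked example

```r
library(phylocurate)

fx <- make_gastropod_fixture(seed = 1)
fx$set
#> Ortholog set: 1059 genes over 74 terminals

occ <- compute_occupancy(fx$set)
occ
#> Occupancy: 1059 genes x 74 taxa; mean per-gene occupancy 0.581

length(slice_by_occupancy(fx$set, 0.7)$genes)   # matrix-4 slice
#> [1] 149

g <- fx$set$genes[[1]]
gene_rate(g)               # mean pairwise p-distance (a fast gene)
#> [1] 0.8015969

composition_homogeneity_test(g, n_simulations = 499, seed = 7)
#> Gene OG000001: X^2 = 612.96, p = 0.286 (499 sims) -> homogeneous at alpha = 0.1

aln_strings(dayhoff_recode(gene_alignment("toy", c(a = "ACDEF-GX"))))
#>          a
#> "12334-1X"   # A,C,D,E,F,G -> 1,2,3,3,4,1; gaps and X pass through
```

A typical curation run chains
`slice_by_occupancy()` → `trim_ends()` → `remove_rate_tails()` /
`filter_homogeneous()` → `concatenate()` →
`write_supermatrix_phylip()` + `write_partition_file()`. For tree
lists from two MCMC chains, `maxdiff(chain_a, chain_b)` near 0 indicates
topological convergence, and `prune_terminal()` tests whether a single
rogue taxon is responsible when it is not.

A thin command-line front end over the same functions ships as
`inst/scripts/phylocurate.R` (subcommands `simulate`, `fixture`,
`occupancy`, `slice`, `trim-ends`, `rates`, `drop-tails`, `concat`,
`outgroup-subset`, `longest-iso`, `compo-test`, `dayhoff-recode`,
`supports`, `maxdiff`, `rf`, `prune`).

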