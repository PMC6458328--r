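---
title: "Curating phylogenomic supermatrices and diagnosing congruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating phylogenomic supermatrices and diagnosing congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocurate)
```

## The problem

Phylotranscriptomic datasets -- hundreds to thousands of orthologous gene
alignments over dozens of taxa -- carry systematic error alongside signal:
genes evolve at very different rates, lineages drift in amino-acid
composition, gene trees conflict with the species tree, and occupancy is
patchy because transcriptomes capture different gene complements.  Deep
divergences (the classic example being the relationships among the five
major gastropod lineages and their mollusc outgroups) are exactly where
these pathologies bite: long-branch attraction, compositional attraction
and model misspecification can each produce well-supported wrong trees.

A standard defence is to analyse a *family* of curated matrices rather
than one: a base matrix at 50% taxon occupancy; a subset with the rate
extremes removed; a subset of compositionally homogeneous genes; a
high-occupancy (70%) subset; Dayhoff-recoded variants; and
outgroup-restricted variants.  Congruence of the resulting trees across
matrices and inference methods -- rather than support in any single
analysis -- is the evidence.  phylocurate implements that curation
pipeline, the tree-side congruence diagnostics, and a synthetic-data
generator for validating the whole machine.

## Matrix curation

Curation operates on an `ortholog_set`: a `taxon_manifest` (74 terminals
in the study-shaped fixture) plus one `gene_alignment` per orthogroup.
Missing taxa are *absent records*, not gap rows, matching how orthology
pipelines report occupancy; an all-gap row counts as absent.

* **Occupancy slicing** keeps genes present in at least
  `ceiling(fraction * n_taxa)` manifest terminals.  The ceiling-with-`>=`
  convention is forced by the published arithmetic: at 74 taxa, 50% is
  exact at 37 while 70% rounds up to 52, and a gene present in 51 taxa
  must fall below the 70% slice.
* **End trimming** removes terminal columns whose missingness (`-` or
  `X`, over the taxa present in the gene) exceeds 80%; interior columns
  are never touched.  Ragged ends are an artefact of partial transcripts,
  not of evolution.
* **Rate-tail removal** ranks genes by a transparent rate proxy -- the
  mean pairwise p-distance over mutually ungapped columns -- and removes
  the `ceiling(0.2 * n)` slowest and fastest genes.  This is the only
  tail convention that reproduces the published 1059 -> 635 reduction
  (`ceiling(211.8) = 212` per tail).  Ties are broken by gene id so the
  pipeline is deterministic.  The proxy is order-preserving rather than a
  substitution-rate estimate; the validation requirement is rank
  recovery (Spearman >= 0.9 against simulated rate multipliers), not
  absolute calibration.
* **Concatenation** fills terminals missing a gene with `?` (absent
  data, distinct from the indel gap `-`) and records 1-based inclusive
  partitions in input gene order, written in RAxML syntax.
* **Outgroup subsetting** keeps the full ingroup plus a single outgroup
  class; the gene list is deliberately *not* re-sliced, because these
  datasets test outgroup influence on a fixed gene sample.

## The compositional homogeneity test

For each gene the test asks whether its taxa share one stationary
amino-acid composition.  The statistic is the contingency-table
chi-square `X^2` of the taxon-by-residue count table (gaps and `X`
excluded; zero-total residue columns contribute nothing).  Because taxa
are phylogenetically correlated, `X^2` must *not* be referred to a
chi-square distribution; its null distribution is built by simulation:

1. estimate a guide tree by neighbour joining on equal-input-corrected
   p-distances, truncating negative branch lengths at 0;
2. simulate 499 replicate alignments of the gene's length on that tree
   under the frequency-driven replacement model (below) with the gene's
   pooled empirical frequencies;
3. apply the gene's own gap pattern to each replicate before counting;
4. `p = (n_ge + 1) / (n_sims + 1)`; the gene is flagged when `p < 0.1`.

Three design points deserve justification:

* **Distance correction.**  Raw p-distances saturate on deep trees, and
  a guide tree built from them understates compositional drift, making
  the test anti-conservative exactly where it matters.  The equal-input
  correction `d = -b * log(1 - p/b)` with `b = 1 - sum(pi^2)` is the
  closed-form inverse of the simulator's own expected p-distance, so the
  null tree reproduces the observed divergence scale.  Distances are
  capped at `p = b(1 - 1e-3)` to keep saturated pairs finite.
* **Gap-conditional null.**  Taxa that cover different column windows of
  a ragged alignment differ more in composition than full-length rows
  would, because they stop sharing column-level variance.  Simulating
  full replicates and masking them with the observed gap pattern
  conditions the null on the missingness; without this, type-I error on
  heavily end-ragged 74-taxon genes roughly doubles (0.20 vs the nominal
  0.10 in our validation runs).
* **Add-one p-value.**  `(n_ge + 1)/(n_sims + 1)` is a valid Monte-Carlo
  p-value and can never be 0; with 499 simulations the resolution is
  0.002.  A gene at exactly `p = alpha` passes, since the conservative
  rejection region is `p < alpha`.

Genes with fewer than three sequence-bearing taxa, or degenerate
all-zero distances, fall back to a star tree (no internal structure,
tiny terminal branches) with a message.

The test is calibrated by construction and by measurement: over 500 null
genes the rejection rate at `alpha` in {0.01, 0.05, 0.1} sits inside the
99% binomial band (see `test-composition.R`).  A direct consequence --
worth stating plainly -- is that filtering a large set of genuinely
homogeneous genes at `alpha = 0.1` flags about 10% of them.  On the
study-shaped fixture the homogeneous partition is therefore ~900 genes
(60 of 962 unshifted genes false-flagged in our reference run, with all
97 shifted genes caught), not exactly 962: a calibrated test cannot
deliver a near-zero false-flag rate at this alpha.

**Dayhoff recoding** maps the 20 residues onto the six classic
categories (`AGPST`=1, `C`=2, `DENQ`=3, `FWY`=4, `HKR`=5, `ILMV`=6),
with `-` and `X` passing through.  Digits keep the recoded alphabet
disjoint from residue letters.  Recoding erases heterogeneity acting
within categories, which the paired tests demonstrate directly.

## The replacement model behind the simulator

All sequence simulation uses a frequency-driven (equal-input, F81-like)
process over the 20 amino acids: over a branch of length `t` (expected
replacements per site),

    P(i -> j | t) = pi_j (1 - exp(-beta t)) + [i = j] exp(-beta t),

with `beta = 1/(1 - sum(pi^2))`.  Each site either keeps its parental
state or redraws from `pi`; event sites are sampled by geometric
skipping, which is an exact draw from the per-site Bernoulli process at
one RNG call per event.  The model is exactly simulable, has the
closed-form p-distance needed for the distance correction, and is rich
enough to both *induce* and *detect* compositional heterogeneity.  It
deliberately omits site-rate variation, exchangeability structure
(LG-like matrices) and heterotachy: those belong to the inference models
this pipeline feeds, not to the curation machinery under test.

Compositional shifts are imposed on the *terminal branches* of selected
taxa, which evolve under the mixed stationary distribution
`(1-s) pi + s pi_disturbed`.  The default disturbance is a point mass on
arginine -- an extreme, single-residue compositional attraction -- so
shift strength `s` has a large, monotone effect on the composition
statistic.

## The study-shaped fixture

`make_gastropod_fixture()` generates the dataset all end-to-end checks
run on.  Its dimensions are fixed by the study design it emulates: 74
terminals (17 newly sequenced, mostly patellogastropods and nerites; 39
published gastropods; 18 outgroups split 9 Bivalvia / 4 Cephalopoda /
4 Scaphopoda / 1 Polyplacophora), 1059 genes all at >= 50% occupancy,
exactly 149 genes at >= 70% occupancy including genes at exactly 51 and
52 present taxa to probe the threshold, and 97 genes carrying the strong
compositional shift (`s = 0.8`, length 500, 18 shifted taxa).

Where the emulated study reports only counts, the fixture's shapes are
package choices, stated here once:

* species-tree branch lengths `Exp(mean = 0.1)` replacements/site;
* per-gene rate multipliers log-uniform on `[0.3, 3]` (one order of
  magnitude);
* gene-tree discordance probability 0.2, realised as one random NNI
  move -- the minimal topological conflict, sufficient to exercise the
  congruence tooling (a coalescent simulator would add realism the
  downstream tests never consume);
* unshifted gene lengths uniform on 200-400 columns;
* ragged ends of up to 15% of columns per row per side plus 0-2 short
  internal indel runs;
* occupancy targets decay geometrically away from the 50% cutoff, as in
  real occupancy profiles where most genes sit near the admission
  threshold.

The fixture is seed-deterministic end to end.  What passing tests on it
do *not* show: robustness to site-rate variation, heterotachy,
alignment error, or paralogy -- none of which the generator emulates.

## Tree-side diagnostics

Bipartitions are canonicalized by the side not containing the
lexicographically smallest tip label, making a split and its complement
identical keys; rooted inputs are treated as unrooted.  On these keys
the package builds Robinson-Foulds distances (checked against an
independent implementation), Fig.-2-style split-support tables (support
of each reference split in each analysis, `NA` where the split is
absent, plus an all-analyses-full-support summary), posterior
bipartition frequencies, and the between-chain `maxdiff` diagnostic:
the maximum absolute split-frequency difference over the union of
observed splits, absent splits counting 0.  That union convention is
what makes a single chain-fixed rogue terminal -- one taxon attached at
one edge in every tree of chain A and a different edge in chain B --
produce `maxdiff = 1` on otherwise identical posteriors, and
`prune_terminal()` then drops it to 0.  Support values parsed from
Newick node labels above 1 are treated as percentages and divided by
100.  Tree-list burn-in defaults to 0 and is exposed as a fraction.

## Numerical choices and degenerate inputs

* Occupancy threshold and rate-tail counts use `ceiling` (see above);
  slicing and trimming are idempotent.
* p-distance pairs with no comparable column are skipped by the rate
  proxy (an error if no pair remains) and set to the saturation cap by
  the guide-tree builder.
* `X^2 = 0` (identical compositions) gives `p = 1` exactly.
* Negative NJ branch lengths are truncated at 0; zero-length branches
  simulate as zero event probability.
* A point-mass frequency vector makes `beta` infinite; the simulator
  then treats any positive branch as a certain event, which is the
  correct limit.

## Problem sizes

The validation suite runs at deliberately modest sizes: 500 null genes
(12 taxa, 300 columns, 199 simulations) for calibration, 200 genes per
shift level for power, and the full 1059-gene fixture with 499
simulations per gene for the end-to-end filter (about two minutes of
compute).  These sizes give binomial confidence bands tight enough for
every stated bound while keeping the whole suite comfortably
desk-scale.

## Limitations

The generator's homogeneous null is also the test's null model, so the
calibration checks validate internal consistency, not robustness to
model violation on real data; the rate proxy is rank-true but not a
substitution-rate estimate; NNI discordance does not emulate coalescent
branch-length signatures; and the congruence tools consume trees -- no
inference engine is included or emulated.
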