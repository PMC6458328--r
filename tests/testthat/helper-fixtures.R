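# Shared test fixtures, built in code.

# tiny three-gene set over taxa A, B, C used by the curation unit tests
tiny_set <- function() {
  man <- taxon_manifest(c("A", "B", "C"),
                        c("G1", "G1", "G2"),
                        c("new", "published_ingroup", "outgroup"))
  ortholog_set(man, list(
    gene_alignment("g1", c(A = "ACDE", B = "ACDF")),
    gene_alignment("g2", c(A = "KKKK")),
    gene_alignment("g3", c(A = "MNPQ", B = "MNPQ", C = "MNPP"))
  ))
}

# skeleton ortholog set with n trivial one-column genes (rates injected by
# the caller), for rate-tail oracle tests
skeleton_set <- function(n, taxa = c("x", "y")) {
  man <- taxon_manifest(taxa, rep("G", length(taxa)),
                        rep("published_ingroup", length(taxa)))
  genes <- lapply(seq_len(n), function(i)
    gene_alignment(sprintf("g%04d", i),
                   setNames(rep("A", length(taxa)), taxa)))
  ortholog_set(man, genes)
}

# manifest with 56 ingroup terminals and 18 outgroups split 9/4/4/1
outgroup_manifest <- function() {
  ids <- c(sprintf("in%02d", 1:56), sprintf("biv%d", 1:9),
           sprintf("ceph%d", 1:4), sprintf("scaph%d", 1:4), "poly1")
  grp <- c(rep("Gastropoda", 56), rep("Bivalvia", 9), rep("Cephalopoda", 4),
           rep("Scaphopoda", 4), "Polyplacophora")
  src <- c(rep("published_ingroup", 56), rep("outgroup", 18))
  taxon_manifest(ids, grp, src)
}

# brute-force oracle for rate-tail removal: sort by (rate, id), slice
rate_tail_oracle <- function(ids, rates, lower, upper) {
  ord <- ids[order(rates[ids], ids)]
  n <- length(ids)
  drop <- c(head(ord, ceiling(lower * n)),
            tail(ord, ceiling(upper * n)))
  ids[!ids %in% drop]
}

# attach a rogue terminal to a fixed edge of a base tree (chain-fixed
# placement, as in a stuck MCMC chain)
attach_rogue <- function(base, edge_index, label = "rogue") {
  phytools::bind.tip(base, label, edge.length = 0.1,
                     where = base$edge[edge_index, 2],
                     position = base$edge.length[edge_index] / 2)
}

# the full study-shaped fixture is expensive (~15 s); build it once per
# test run and share across files
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- make_gastropod_fixture(seed = 1)
  .fixture_cache$fx
}
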