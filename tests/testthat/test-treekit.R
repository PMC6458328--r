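# Tree utilities: Newick I/O, bipartition algebra, RF distances, NJ,
# split-support tables, posterior frequencies, maxdiff, pruning.

test_that("Newick parsing validates input and normalizes supports", {
  expect_error(parse_newick("((A,B,(C,D));"), "unbalanced")
  expect_error(parse_newick("(A,B,(C,D)));"), "position")
  expect_error(parse_newick("(A,B,(A,D));"), "duplicate labels")

  tr <- parse_newick("(A,B,(C,D));")
  expect_identical(bipartitions(tr), "C,D")

  sup <- parse_newick("((A,B)95,(C,D));")
  ss <- phylocurate:::split_supports(sup)
  expect_equal(ss$support[ss$keys == "C,D"], 0.95)

  # round-trip preserves topology, lengths and supports on random trees
  set.seed(21)
  for (i in 1:100) {
    t0 <- ape::rtree(sample(4:12, 1), rooted = FALSE)
    t0$node.label <- as.character(round(runif(t0$Nnode), 3))
    t1 <- parse_newick(write_newick(t0))
    expect_equal(rf_distance(t0, t1), 0)
    expect_equal(sort(t0$edge.length), sort(t1$edge.length), tolerance = 1e-9)
    s0 <- phylocurate:::split_supports(t0)
    s1 <- phylocurate:::split_supports(t1)
    expect_equal(s1$support[match(s0$keys, s1$keys)], s0$support)
  }
})

test_that("bipartitions are the internal splits of the unrooted topology", {
  five <- parse_newick("((A,B),C,(D,E));")
  expect_equal(length(bipartitions(five)), 2)          # n - 3

  star <- parse_newick("(A,B,C,D,E);")
  expect_identical(bipartitions(star), character())

  # rooted input is treated as unrooted (root edge collapsed)
  rooted <- parse_newick("((A,B),(C,(D,E)));")
  unrooted <- parse_newick("(A,B,(C,(D,E)));")
  expect_setequal(bipartitions(rooted), bipartitions(unrooted))

  # canonicalization: a split equals its complement's canonical form
  set.seed(22)
  checked <- 0
  while (checked < 1000) {
    tr <- ape::rtree(sample(5:12, 1), rooted = FALSE)
    taxa <- tr$tip.label
    for (key in bipartitions(tr)) {
      side <- strsplit(key, ",")[[1]]
      comp <- setdiff(taxa, side)
      expect_identical(phylocurate:::canonical_split(comp, taxa), key)
      checked <- checked + 1
    }
  }

  # binary unrooted reference on n taxa has exactly n - 3 splits
  for (n in 5:10) {
    tr <- ape::rtree(n, rooted = FALSE)
    expect_equal(length(bipartitions(tr)), n - 3)
  }
})

test_that("RF distance equals the symmetric-difference oracle", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  expect_equal(rf_distance(t1, t1), 0)
  t2 <- parse_newick("((A,C),B,(D,E));")    # one NNI away
  expect_equal(rf_distance(t1, t2), 2)
  expect_error(rf_distance(t1, parse_newick("((A,B),C,(D,F));")),
               "terminal sets differ")

  set.seed(23)
  for (i in 1:500) {
    n <- sample(4:8, 1)
    a <- ape::rtree(n, rooted = FALSE)
    b <- ape::rtree(n, rooted = FALSE)
    expect_equal(rf_distance(a, b),
                 as.numeric(phangorn::RF.dist(a, b)))
  }
})

test_that("neighbour joining recovers additive and ultrametric structures", {
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2)), "at least 3")
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  # three-point equations: terminal branches 1, 2, 3
  expect_setequal(round(t3$edge.length, 9), c(1, 2, 3))

  # additive distances from a known 4-taxon tree recover its topology
  gen <- parse_newick("((a:1,b:2):1.5,(c:0.7,d:1.2):0.8);")
  dd <- ape::cophenetic.phylo(gen)
  expect_equal(rf_distance(nj_tree(dd), gen), 0)

  bad <- d3; bad[1, 2] <- bad[2, 1] <- -1
  expect_error(nj_tree(bad), "negative")
  asym <- d3; asym[1, 2] <- 9
  expect_error(nj_tree(asym), "symmetric")

  # ultrametric distances: topology agrees with hierarchical clustering
  set.seed(24)
  hc_tree <- ape::rcoal(8)
  du <- ape::cophenetic.phylo(hc_tree)
  hcl <- ape::as.phylo(stats::hclust(stats::as.dist(du), method = "average"))
  expect_equal(rf_distance(nj_tree(du), hcl), 0)
})

test_that("split-support tables report per-analysis support or absence", {
  set.seed(25)
  ref <- ape::rtree(20, rooted = FALSE)
  full <- ref
  full$node.label <- rep("1", full$Nnode)

  tab <- split_support_table(ref, list(self = full))
  expect_equal(nrow(tab), 17)                       # n - 3 rows
  expect_true(all(tab$self == 1))
  expect_true(all(tab$all_full))

  # an analysis lacking a split gets NA there, and all_full drops
  alt <- phangorn::rNNI(full, moves = 1)
  alt$node.label <- rep("0.9", alt$Nnode)
  tab2 <- split_support_table(ref, list(self = full, alt = alt))
  expect_true(any(is.na(tab2$alt)))
  expect_false(all(tab2$all_full))

  # seventeen analyses make seventeen support columns
  analyses <- setNames(rep(list(full), 17), paste0("analysis", 1:17))
  tab17 <- split_support_table(ref, analyses)
  expect_equal(sum(!names(tab17) %in% c("split", "all_full")), 17)

  smaller <- ape::drop.tip(full, "t1")
  expect_error(split_support_table(ref, list(bad = smaller)), "differs")

  tsv <- tempfile(fileext = ".tsv")
  write_split_support_tsv(tab2, ref$tip.label, tsv)
  expect_match(readLines(tsv)[1], "split\tself\talt\tall_full")
})

test_that("bipartition frequencies count split occurrences over the sample", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  t2 <- parse_newick("((A,C),B,(D,E));")
  same <- bipartition_frequencies(rep(list(t1), 5))
  expect_true(all(same == 1))
  # the {A,B} split canonicalizes to its complement "C,D,E" (the side
  # without the reference terminal A)
  mix <- bipartition_frequencies(c(rep(list(t1), 3), list(t2)))
  expect_equal(unname(mix["C,D,E"]), 0.75)
  expect_equal(unname(mix["D,E"]), 1)
  expect_true(all(mix > 0 & mix <= 1))
  expect_error(bipartition_frequencies(list()), "empty")
  expect_error(bipartition_frequencies(list(t1, parse_newick("((A,B),C,(D,F));"))),
               "different terminal set")
  # burn-in discards the leading fraction
  burn <- bipartition_frequencies(c(rep(list(t2), 2), rep(list(t1), 2)),
                                  burnin = 0.5)
  expect_equal(unname(burn["C,D,E"]), 1)
})

test_that("maxdiff measures between-chain split-frequency disagreement", {
  t1 <- parse_newick("((A,B),C,(D,E));")
  t2 <- parse_newick("((A,C),B,(D,E));")
  expect_equal(maxdiff(rep(list(t1), 4), rep(list(t1), 4)), 0)

  # hand case: split at frequency 0.6 in A and 0.2 in B -> 0.4
  chain_a <- c(rep(list(t1), 3), rep(list(t2), 2))
  chain_b <- c(rep(list(t1), 1), rep(list(t2), 4))
  expect_equal(maxdiff(chain_a, chain_b), 0.4)

  # symmetry and range on random chains
  set.seed(26)
  for (i in 1:20) {
    ca <- lapply(1:5, function(j) ape::rtree(7, rooted = FALSE))
    cb <- lapply(1:5, function(j) ape::rtree(7, rooted = FALSE))
    expect_equal(maxdiff(ca, ca), 0)
    m1 <- maxdiff(ca, cb)
    expect_equal(m1, maxdiff(cb, ca))
    expect_gte(m1, 0)
    expect_lte(m1, 1)
  }
})

test_that("a chain-fixed rogue terminal drives maxdiff to 1 until pruned", {
  base <- simulate_species_tree(10, seed = 4)
  chain_a <- rep(list(attach_rogue(base, 2)), 100)
  chain_b <- rep(list(attach_rogue(base, 9)), 100)
  expect_equal(maxdiff(chain_a, chain_b), 1)
  expect_equal(maxdiff(prune_terminal(chain_a, "rogue"),
                       prune_terminal(chain_b, "rogue")), 0)
})

test_that("pruning preserves the remaining structure", {
  # cherry member from a 4-taxon binary tree: no internal splits remain
  quart <- parse_newick("((A,B),(C,D));")
  pruned <- prune_terminal(list(quart), "A")[[1]]
  expect_equal(ape::Ntip(pruned), 3)
  expect_identical(bipartitions(pruned), character())

  err <- tryCatch(prune_terminal(list(quart, parse_newick("((A,B),(C,E));")), "D"),
                  error = conditionMessage)
  expect_match(err, "tree 2")

  set.seed(27)
  for (i in 1:25) {
    tr <- ape::rtree(9, rooted = FALSE)
    drop <- sample(tr$tip.label, 1)
    kept <- setdiff(tr$tip.label, drop)
    before <- ape::cophenetic.phylo(tr)[kept, kept]
    after <- ape::cophenetic.phylo(prune_terminal(list(tr), drop)[[1]])[kept, kept]
    expect_equal(after, before, tolerance = 1e-9)   # path lengths preserved

    # prune of {x, y} commutes
    xy <- sample(tr$tip.label, 2)
    ab <- prune_terminal(prune_terminal(list(tr), xy[1]), xy[2])[[1]]
    ba <- prune_terminal(prune_terminal(list(tr), xy[2]), xy[1])[[1]]
    expect_equal(rf_distance(ab, ba), 0)
  }
})
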