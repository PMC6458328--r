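# Matrix curation: occupancy, slicing, end trimming, rate proxies and
# tails, concatenation, outgroup subsetting, isoform selection.

test_that("occupancy counts sequence records, treating all-gap rows as absent", {
  man <- taxon_manifest(c("A", "B", "C"), rep("G", 3), rep("new", 3))
  set <- ortholog_set(man, list(
    gene_alignment("g1", c(A = "AC", B = "AC")),
    gene_alignment("g2", c(A = "AC")),
    gene_alignment("g3", c(A = "AC", B = "AC", C = "AC"))
  ))
  occ <- compute_occupancy(set)
  expect_equal(unname(occ$gene_counts), c(2, 1, 3))
  expect_true(occ$presence["g1", "A"])
  expect_false(occ$presence["g1", "C"])

  gapped <- ortholog_set(man, list(
    gene_alignment("g1", c(A = "AC", B = "--", C = "XX"))
  ))
  occg <- compute_occupancy(gapped)
  expect_equal(unname(occg$gene_counts), 1)   # B and C carry no residues
  expect_error(compute_occupancy(ortholog_set(man, list())), "empty")
})

test_that("occupancy slicing applies the ceiling threshold and is idempotent", {
  # 74-taxon manifest; genes with 51 and 52 present taxa straddle the
  # ceiling(0.7 * 74) = 52 boundary
  ids <- sprintf("s%02d", 1:74)
  man <- taxon_manifest(ids, rep("G", 74), rep("published_ingroup", 74))
  mk <- function(id, k) gene_alignment(id, setNames(rep("A", k), ids[1:k]))
  set <- ortholog_set(man, list(mk("g51", 51), mk("g52", 52), mk("g74", 74)))

  expect_equal(gene_ids(slice_by_occupancy(set, 0)), c("g51", "g52", "g74"))
  expect_equal(gene_ids(slice_by_occupancy(set, 0.7)), c("g52", "g74"))
  expect_error(slice_by_occupancy(set, 1.2), "fraction")

  once <- slice_by_occupancy(set, 0.7)
  twice <- slice_by_occupancy(once, 0.7)
  expect_identical(gene_ids(once), gene_ids(twice))

  # monotone: higher fractions never keep more genes
  kept <- vapply(seq(0, 1, by = 0.1),
                 function(f) length(slice_by_occupancy(set, f)$genes),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("end trimming removes only terminal columns above the threshold", {
  clean <- gene_alignment("c", c(a = "ACDE", b = "ACDE"))
  expect_identical(trim_ends(clean, 0.8)$aln, clean$aln)

  # first two columns fully gapped in all five rows -> removed
  rows <- setNames(rep("--ACD", 5), paste0("t", 1:5))
  g <- gene_alignment("g", rows)
  expect_equal(aln_length(trim_ends(g, 0.8)), 3)

  # an interior fully gapped column flanked by clean columns is retained
  mid <- gene_alignment("m", c(a = "A-C", b = "A-C"))
  expect_equal(aln_length(trim_ends(mid, 0.8)), 3)

  # 'X' counts as missing; trimming is idempotent; result can be empty
  gx <- gene_alignment("x", c(a = "XXA", b = "X-A", c = "-XA"))
  t1 <- trim_ends(gx, 0.8)
  expect_equal(aln_length(t1), 1)
  expect_identical(trim_ends(t1, 0.8)$aln, t1$aln)
  allgap <- gene_alignment("e", c(a = "--", b = "--"))
  expect_equal(aln_length(trim_ends(allgap, 0.8)), 0)
})

test_that("the rate proxy is the mean pairwise p-distance over comparable columns", {
  expect_equal(gene_rate(gene_alignment("g", c(a = "ACDE", b = "ACDE"))), 0)
  expect_equal(gene_rate(gene_alignment("g", c(a = "ACDE", b = "ACDF"))), 0.25)
  expect_equal(gene_rate(gene_alignment("g", c(a = "AC-E", b = "ACDE"))), 0)
  # three sequences: mean over the three unordered pairs
  g3 <- gene_alignment("g", c(a = "AAAA", b = "AAAC", c = "AACC"))
  expect_equal(gene_rate(g3), mean(c(0.25, 0.5, 0.25)))
  expect_error(gene_rate(gene_alignment("g", c(a = "ACDE"))), "2 sequences")
  expect_error(gene_rate(gene_alignment("g", c(a = "A-", b = "-A"))),
               "rate undefined")
})

test_that("rate-tail removal matches the ceiling convention and the sort oracle", {
  # 10 genes at 0.2/0.2 -> ceiling(2) dropped per tail, 6 remain
  set10 <- skeleton_set(10)
  rates10 <- setNames(seq(0.01, 0.1, by = 0.01), gene_ids(set10))
  expect_equal(length(remove_rate_tails(set10, 0.2, 0.2, rates = rates10)$genes), 6)
  expect_identical(gene_ids(remove_rate_tails(set10, 0, 0, rates = rates10)),
                   gene_ids(set10))
  expect_error(remove_rate_tails(set10, 0.6, 0.5, rates = rates10), "sum below 1")

  # 1059 genes with distinct rates -> 635 survivors at 20%/20%
  big <- skeleton_set(1059)
  set.seed(42)
  rbig <- setNames(runif(1059), gene_ids(big))
  expect_equal(length(remove_rate_tails(big, 0.2, 0.2, rates = rbig)$genes), 635)

  # brute-force sort-and-slice oracle on 1000 random small sets
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    sk <- skeleton_set(n)
    rates <- setNames(round(runif(n), 2), gene_ids(sk))   # ties likely
    lo <- runif(1, 0, 0.4)
    hi <- runif(1, 0, 0.4)
    got <- gene_ids(remove_rate_tails(sk, lo, hi, rates = rates))
    expect_identical(got, rate_tail_oracle(gene_ids(sk), rates, lo, hi))
  }

  # surviving rates sit strictly inside the removed tails' range
  surv <- remove_rate_tails(big, 0.2, 0.2, rates = rbig)
  removed <- attr(surv, "removed")
  kept_rates <- rbig[gene_ids(surv)]
  expect_gt(min(kept_rates), max(rbig[head(removed, 212)]))
  expect_lt(max(kept_rates), min(rbig[tail(removed, 212)]))
})

test_that("concatenation tiles partitions and fills absent taxa with '?'", {
  man <- taxon_manifest(c("A", "B", "C"), rep("G", 3), rep("new", 3))
  set <- ortholog_set(man, list(
    gene_alignment("g1", c(A = "ACD", B = "ACD", C = "ACD")),
    gene_alignment("g2", c(A = "KKKK", B = "KKKR"))
  ))
  sm <- concatenate(set)
  expect_equal(sm$partitions$start, c(1, 4))
  expect_equal(sm$partitions$end, c(3, 7))
  expect_equal(unname(nchar(sm$rows)), rep(7, 3))
  expect_identical(unname(sm$rows["C"]), "ACD????")
  expect_identical(unname(sm$rows["A"]), "ACDKKKK")
  # partition lengths tile the matrix exactly
  expect_equal(sum(sm$partitions$end - sm$partitions$start + 1), 7)

  single <- concatenate(ortholog_set(man, set$genes[1]))
  expect_identical(unname(single$rows[c("A", "B", "C")]),
                   unname(aln_strings(set$genes[[1]])[c("A", "B", "C")]))

  dup <- set
  rownames(dup$genes[[2]]$aln) <- c("A", "A")
  expect_error(concatenate(dup), "duplicate terminal")
  expect_error(concatenate(ortholog_set(man, list())), "empty")
})

test_that("supermatrix writers emit FASTA, relaxed PHYLIP and RAxML partitions", {
  man <- taxon_manifest(c("A", "B"), rep("G", 2), rep("new", 2))
  sm <- concatenate(ortholog_set(man, list(
    gene_alignment("g1", c(A = "ACD", B = "ACD")),
    gene_alignment("g2", c(A = "KK"))
  )))
  fa <- tempfile(fileext = ".fasta")
  ph <- tempfile(fileext = ".phy")
  pt <- tempfile(fileext = ".txt")
  write_supermatrix_fasta(sm, fa)
  write_supermatrix_phylip(sm, ph)
  write_partition_file(sm, pt, model = "LG")
  back <- Biostrings::readBStringSet(fa)
  expect_identical(as.character(back[["B"]]), "ACD??")
  phy <- readLines(ph)
  expect_identical(phy[1], "2 5")
  expect_identical(readLines(pt), c("LG, g1 = 1-3", "LG, g2 = 4-5"))
})

test_that("outgroup subsetting keeps the ingroup plus one outgroup class", {
  man <- outgroup_manifest()
  genes <- list(gene_alignment("g1", setNames(rep("AC", 74), man$terminal_id)))
  set <- ortholog_set(man, genes)

  biv <- subset_outgroups(set, "Bivalvia")
  expect_equal(nrow(biv$manifest), 65)       # 56 ingroup + 9 bivalves
  expect_equal(length(biv$genes), 1)         # gene list unchanged
  expect_equal(nrow(biv$genes[[1]]$aln), 65)

  poly <- subset_outgroups(set, "Polyplacophora")
  expect_equal(nrow(poly$manifest), 57)      # ingroup + the single chiton

  err <- tryCatch(subset_outgroups(set, "Brachiopoda"), error = conditionMessage)
  expect_match(err, "unknown group")
  expect_match(err, "Bivalvia")              # error lists available labels

  # degenerate: keeping a group that is the only outgroup class present
  man2 <- taxon_manifest(c("i1", "o1", "o2"), c("G", "Bivalvia", "Bivalvia"),
                         c("new", "outgroup", "outgroup"))
  set2 <- ortholog_set(man2, list(gene_alignment("g", c(i1 = "A", o1 = "A", o2 = "A"))))
  expect_identical(subset_outgroups(set2, "Bivalvia")$manifest$terminal_id,
                   man2$terminal_id)
})

test_that("longest-isoform selection keeps one sequence per gene key", {
  one <- c(TRINITY_DN1_c0_g1_i1 = "MKV")
  expect_identical(select_longest_isoform(one)$sequence, "MKV")

  iso <- c(TRINITY_DN1_c0_g1_i1 = strrep("A", 100),
           TRINITY_DN1_c0_g1_i2 = strrep("A", 120))
  got <- select_longest_isoform(iso)
  expect_identical(got$sequence_id, "TRINITY_DN1_c0_g1_i2")

  two <- c(g1.1 = "AA", g1.2 = "AAA", g2.1 = "CCCC", g2.2 = "CC")
  got2 <- select_longest_isoform(two)
  expect_equal(nrow(got2), 2)
  expect_identical(got2$sequence_id, c("g1.2", "g2.1"))

  # ties by lexicographically smallest id; unparsable ids pass through
  tie <- c(g1.2 = "AAA", g1.1 = "CCC")
  expect_identical(select_longest_isoform(tie)$sequence_id, "g1.1")
  expect_message(odd <- select_longest_isoform(c(weirdname = "MM", g1.1 = "K")),
                 "no isoform token")
  expect_equal(nrow(odd), 2)
})

test_that("estimated gene rates recover the simulated rate ranking", {
  sp <- simulate_species_tree(8, seed = 50)
  mult <- 10^seq(-1, 1, length.out = 200)     # 0.1 to 10
  est <- numeric(200)
  for (i in seq_along(mult)) {
    tr <- sp
    tr$edge.length <- tr$edge.length * mult[i]
    est[i] <- gene_rate(simulate_alignment(tr, 300, seed = 9000 + i))
  }
  expect_gte(stats::cor(mult, est, method = "spearman"), 0.9)
})

test_that("per-gene FASTA and manifest round-trip through disk", {
  set <- tiny_set()
  dir <- tempfile()
  write_ortholog_fastas(set, dir)
  back <- read_ortholog_fastas(dir, set$manifest)
  expect_identical(lapply(back$genes, `[[`, "aln"),
                   lapply(set$genes, `[[`, "aln"))
  mtsv <- tempfile(fileext = ".tsv")
  write_taxon_manifest(set$manifest, mtsv)
  expect_identical(read_taxon_manifest(mtsv), set$manifest)
})
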