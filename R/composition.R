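# Compositional homogeneity: taxon-by-residue count tables, the X^2
# heterogeneity statistic, a simulation-based homogeneity test (null
# replicates on a neighbour-joining guide tree under the frequency-driven
# model with the gene's pooled frequencies), homogeneity filtering, and
# Dayhoff 6-state recoding.

#' Residue counts per taxon
#'
#' Counts each state per taxon, ignoring `'-'` and `'X'`.  Taxa with zero
#' residues are excluded with a message.
#'
#' @param gene A [gene_alignment()].
#' @return Integer matrix (taxa x states) of class `composition_table`.
#' @export
#' @examples
#' composition_counts(gene_alignment("g", c(a = "AAA-", b = "ACDX")))
composition_counts <- function(gene) {
  states <- alphabet_states(gene$alphabet)
  counts <- t(apply(gene$aln, 1L, function(row)
    tabulate(match(row, states), nbins = length(states))))
  colnames(counts) <- states
  empty <- rowSums(counts) == 0
  if (any(empty))
    message("excluding ", sum(empty), " taxa with zero residues from gene ",
            gene$gene_id, ": ", paste(rownames(counts)[empty], collapse = ", "))
  counts <- counts[!empty, , drop = FALSE]
  if (nrow(counts) < 2)
    stop("composition table needs at least 2 taxa with residues")
  structure(counts, class = c("composition_table", class(counts)))
}

#' Compositional heterogeneity X^2 statistic
#'
#' The chi-square statistic of the taxon-by-state count table against the
#' independence expectation `E_ij = row_i * col_j / grand`; state columns
#' with zero total contribute 0.  The statistic is only the summary; its
#' null distribution on phylogenetically correlated data must come from
#' simulation ([composition_homogeneity_test()]), not from a chi-square
#' distribution.
#'
#' @param table A `composition_table` (or plain count matrix, taxa x
#'   states).
#' @return Non-negative X^2 value.
#' @export
x2_statistic <- function(table) {
  if (nrow(table) < 2) stop("X^2 needs at least 2 taxa")
  if (sum(table) <= 0) stop("X^2 needs a positive total count")
  rowtot <- rowSums(table)
  coltot <- colSums(table)
  use <- coltot > 0
  e <- outer(rowtot, coltot[use]) / sum(table)
  sum((table[, use, drop = FALSE] - e)^2 / e)
}

# F81-corrected (equal-input) distances from p-distances for the guide tree;
# saturated or incomparable pairs are capped at the maximal resolvable
# distance rather than dropped.
corrected_distances <- function(p, freqs) {
  b <- max(1 - sum(freqs^2), 1e-12)
  pmax <- b * (1 - 1e-3)
  p[is.na(p)] <- pmax
  p <- pmin(p, pmax)
  d <- -b * log(1 - p / b)
  diag(d) <- 0
  d
}

# NJ guide tree on corrected p-distances; star tree fallback for < 3 taxa
# or degenerate (all-zero) distances.
guide_tree <- function(gene, freqs) {
  taxa <- aln_taxa(gene)
  if (length(taxa) >= 3) {
    p <- pdistance_matrix(gene)
    d <- corrected_distances(p, freqs)
    if (any(d[upper.tri(d)] > 0))
      return(nj_tree(d))
    message("degenerate distances for gene ", gene$gene_id,
            "; using a star tree")
  } else {
    message("fewer than 3 taxa for gene ", gene$gene_id,
            "; using a star tree")
  }
  star_tree(taxa)
}

# star topology with tiny terminal branches (no internal structure)
star_tree <- function(taxa, branch = 1e-8) {
  n <- length(taxa)
  tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n)),
             edge.length = rep(branch, n), tip.label = taxa, Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

#' Simulation-based compositional homogeneity test
#'
#' Tests whether the taxa of a gene share one stationary amino-acid
#' composition.  The observed X^2 is compared with replicates simulated
#' under a compositionally homogeneous null: a neighbour-joining guide
#' tree is estimated from equal-input-corrected p-distances, and
#' `n_simulations` alignments of the same length are evolved on it under
#' the frequency-driven model with the gene's pooled empirical
#' frequencies.  Replicates inherit the gene's gap pattern before
#' counting, so the null distribution is conditional on the observed
#' missingness (taxa covering different column windows of a ragged
#' alignment genuinely differ more in composition than full-length rows
#' would).  The Monte-Carlo p-value uses the add-one estimator
#' `p = (n_ge + 1) / (n_simulations + 1)`, so `p` is never 0;
#' `homogeneous` is `p >= alpha` (the rejection region is `p < alpha`).
#'
#' @param gene A [gene_alignment()].
#' @param n_simulations Number of null replicates (at least 99; default
#'   499, resolving p to 0.002).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param alpha Significance level of the homogeneity decision.
#' @return List of class `composition_test` with `gene_id`, `x2_observed`,
#'   `n_simulations`, `n_ge`, `p_value`, `homogeneous`, `alpha`.
#' @export
composition_homogeneity_test <- function(gene, n_simulations = 499L,
                                         seed = NULL, alpha = 0.1) {
  if (n_simulations < 99) stop("n_simulations must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  counts <- composition_counts(gene)
  x2_obs <- x2_statistic(counts)
  freqs <- colSums(counts) / sum(counts)     # pooled empirical frequencies
  g <- gene
  if (nrow(counts) < nrow(gene$aln))         # drop residue-free taxa
    g <- gene_alignment(gene$gene_id,
                        gene$aln[rownames(counts), , drop = FALSE],
                        alphabet = gene$alphabet)
  tr <- guide_tree(g, freqs)
  ed <- tree_preorder_edges(tr)
  ev <- edge_event_probs(ed$length, freqs)
  # null replicates inherit the observed gap pattern (rows ordered as the
  # guide tree's tips), so the null is conditional on the missingness
  mask <- residue_mask(g)[tr$tip.label, , drop = FALSE] * 1L
  x2_null <- x2_null_cpp(ed$parent, ed$child, ev, ed$n_nodes, ed$root,
                         ed$n_tip, freqs, aln_length(g),
                         as.integer(n_simulations), mask)
  n_ge <- sum(x2_null >= x2_obs)
  p <- (n_ge + 1) / (n_simulations + 1)
  structure(list(gene_id = gene$gene_id, x2_observed = x2_obs,
                 n_simulations = as.integer(n_simulations),
                 n_ge = as.integer(n_ge), p_value = p,
                 homogeneous = p >= alpha, alpha = alpha),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("Gene %s: X^2 = %.2f, p = %.4g (%d sims) -> %s at alpha = %g\n",
              x$gene_id, x$x2_observed, x$p_value, x$n_simulations,
              if (x$homogeneous) "homogeneous" else "heterogeneous", x$alpha))
  invisible(x)
}

#' Partition an ortholog set by compositional homogeneity
#'
#' Runs [composition_homogeneity_test()] on every gene (with per-gene
#' seeds derived from `seed`) and splits the set into the homogeneous
#' (kept) and heterogeneous (flagged) genes.  Order is preserved and
#' `kept + flagged = input`.
#'
#' @param set An [ortholog_set()].
#' @param alpha Significance level in `(0, 1)`.
#' @param n_simulations Null replicates per gene.
#' @param seed Integer base seed.
#' @param quiet Suppress per-gene messages (star-tree fallbacks etc.).
#' @return List with `kept` and `flagged` ([ortholog_set()]s) and
#'   `results`, a per-gene `data.frame` (gene_id, x2, n_simulations, p,
#'   homogeneous).
#' @export
filter_homogeneous <- function(set, alpha = 0.1, n_simulations = 499L,
                               seed = 1L, quiet = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n <- length(set$genes)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    run <- function() composition_homogeneity_test(
      set$genes[[i]], n_simulations = n_simulations,
      seed = (seed + i - 1L) %% .Machine$integer.max, alpha = alpha)
    res[[i]] <- if (quiet) suppressMessages(run()) else run()
  }
  results <- data.frame(
    gene_id = vapply(res, `[[`, character(1), "gene_id"),
    x2 = vapply(res, `[[`, numeric(1), "x2_observed"),
    n_simulations = vapply(res, `[[`, integer(1), "n_simulations"),
    p = vapply(res, `[[`, numeric(1), "p_value"),
    homogeneous = vapply(res, `[[`, logical(1), "homogeneous"))
  keep <- results$homogeneous
  list(kept = replace_genes(set, set$genes[keep]),
       flagged = replace_genes(set, set$genes[!keep]),
       results = results)
}

#' The six Dayhoff categories
#'
#' The classic grouping of the 20 amino acids into six biochemically
#' similar classes, encoded as digits: `AGPST -> 1`, `C -> 2`,
#' `DENQ -> 3`, `FWY -> 4`, `HKR -> 5`, `ILMV -> 6`.
#'
#' @return Named character vector mapping each residue to its category
#'   symbol.
#' @export
dayhoff_mapping <- function() {
  groups <- c(A = "1", G = "1", P = "1", S = "1", T = "1",
              C = "2",
              D = "3", E = "3", N = "3", Q = "3",
              F = "4", W = "4", Y = "4",
              H = "5", K = "5", R = "5",
              I = "6", L = "6", M = "6", V = "6")
  groups[AA_RESIDUES]
}

#' Dayhoff 6-state recoding
#'
#' Replaces each residue by its Dayhoff category digit; `'-'` and `'X'`
#' pass through unchanged.  Recoding merges residues within a category,
#' damping compositional heterogeneity (and saturation) that acts within
#' categories.
#'
#' @param gene A [gene_alignment()] over the amino-acid alphabet.
#' @return A [gene_alignment()] with `alphabet = "dayhoff6"`.
#' @export
#' @examples
#' aln_strings(dayhoff_recode(gene_alignment("g", c(a = "CCCC"))))
dayhoff_recode <- function(gene) {
  if (gene$alphabet != "aa") stop("dayhoff_recode expects an amino-acid alignment")
  map <- dayhoff_mapping()
  bad <- !(gene$aln %in% c(names(map), "-", "X"))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("unknown character '", gene$aln[i], "' at row ",
         rownames(gene$aln)[(i - 1L) %% nrow(gene$aln) + 1L], ", column ",
         (i - 1L) %/% nrow(gene$aln) + 1L)
  }
  m <- gene$aln
  idx <- match(m, names(map))
  m[!is.na(idx)] <- map[idx[!is.na(idx)]]
  gene_alignment(gene$gene_id, m, alphabet = "dayhoff6")
}

#' Write a per-gene composition test report as TSV
#'
#' @param results The `results` data.frame from [filter_homogeneous()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_composition_report <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
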