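# Synthetic-data generators: species trees, discordant gene trees, and
# amino-acid alignments under a frequency-driven (equal-input / F81-like)
# replacement model, with optional taxon-specific compositional shifts and
# patterned missingness.  These emulate the heterogeneity that supermatrix
# filters target: among-gene rate variation, compositional heterogeneity,
# gene-tree discordance and patchy occupancy.

# ---- tree plumbing ----------------------------------------------------------

# preorder edge arrays for the C++ simulator (0-based node indices, root =
# n_tip in ape numbering minus 1)
tree_preorder_edges <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tr <- stats::reorder(tree, "postorder")
  idx <- rev(seq_len(nrow(tr$edge)))
  list(parent = tr$edge[idx, 1L] - 1L,
       child  = tr$edge[idx, 2L] - 1L,
       length = tr$edge.length[idx],
       n_nodes = ape::Ntip(tr) + tr$Nnode,
       n_tip  = ape::Ntip(tr),
       root   = ape::Ntip(tr))
}

# per-edge probability that at least one replacement event hits a site,
# beta = 1/(1 - sum pi^2) so branch lengths are expected replacements/site
edge_event_probs <- function(lengths, freqs) {
  b <- 1 - sum(freqs^2)
  if (b < 1e-12) return(as.numeric(lengths > 0))
  -expm1(-lengths / b)
}

check_frequencies <- function(frequencies, k = 20L) {
  if (length(frequencies) != k)
    stop("frequencies must have length ", k)
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies not normalized (sum = ", format(sum(frequencies)), ")")
  invisible(frequencies)
}

#' Frequency vector concentrated on one residue
#'
#' Convenience builder for disturbed stationary frequencies: puts `mass` on
#' a single residue and spreads the remainder over `base`.  The default
#' (full mass on arginine) mimics an extreme lineage-specific compositional
#' attraction such as the GC-driven enrichment of arginine.
#'
#' @param residue Single residue letter.
#' @param mass Probability mass placed on `residue`, in `[0, 1]`.
#' @param base Frequencies receiving the remaining `1 - mass`.
#' @return Named 20-vector summing to 1.
#' @export
concentrated_frequencies <- function(residue = "R", mass = 1,
                                     base = protein_frequencies()) {
  stopifnot(residue %in% AA_RESIDUES, mass >= 0, mass <= 1)
  point <- setNames(as.numeric(AA_RESIDUES == residue), AA_RESIDUES)
  (1 - mass) * base / sum(base) + mass * point
}

# ---- species and gene trees -------------------------------------------------

#' Simulate a species tree
#'
#' Draws a random binary unrooted topology over `n_taxa` labelled terminals
#' with branch lengths from an exponential distribution with mean
#' `mean_branch` (default 0.1 expected replacements per site).
#'
#' @param n_taxa Number of terminals (at least 3).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param mean_branch Mean of the exponential branch-length distribution.
#' @param labels Terminal labels (default `t1 ... tn`).
#' @return An unrooted `phylo` tree with `2 * n_taxa - 3` edges.
#' @export
#' @examples
#' tr <- simulate_species_tree(8, seed = 1)
#' ape::Ntip(tr)
simulate_species_tree <- function(n_taxa, seed = NULL, mean_branch = 0.1,
                                  labels = NULL) {
  if (n_taxa < 3) stop("too few taxa")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  stopifnot(length(labels) == n_taxa)
  tr <- ape::rtree(n_taxa, rooted = FALSE, tip.label = labels,
                   br = function(n) rexp(n, rate = 1 / mean_branch))
  # guard against zero-length draws (probability ~0, but keep the invariant)
  tr$edge.length <- pmax(tr$edge.length, 1e-9)
  tr
}

#' Simulate discordant gene trees
#'
#' Each gene tree equals the species tree with probability
#' `1 - discordance_prob`; otherwise it differs by one random
#' nearest-neighbour-interchange (NNI) move, the minimal topological
#' conflict (Robinson-Foulds distance 2).  Branch lengths are rescaled per
#' gene by its rate multiplier, giving among-gene rate variation.
#'
#' @param species_tree A `phylo` tree with branch lengths.
#' @param n_genes Number of gene trees.
#' @param discordance_prob Probability, in `[0, 1]`, that a gene tree is
#'   topologically discordant.
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param rate_multipliers Positive scalar or per-gene vector scaling each
#'   gene's branch lengths.
#' @return List of `phylo` trees with attributes `"discordant"` (logical)
#'   and `"rate_multipliers"`.
#' @export
simulate_gene_trees <- function(species_tree, n_genes, discordance_prob,
                                seed = NULL, rate_multipliers = 1) {
  if (is.null(species_tree) || is.null(species_tree$tip.label) ||
      ape::Ntip(species_tree) == 0)
    stop("empty species tree")
  if (discordance_prob < 0 || discordance_prob > 1)
    stop("discordance_prob must be in [0, 1]")
  if (any(rate_multipliers <= 0)) stop("rate_multipliers must be positive")
  rate_multipliers <- rep_len(rate_multipliers, n_genes)
  if (!is.null(seed)) set.seed(seed)
  discordant <- runif(n_genes) < discordance_prob
  trees <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    tr <- species_tree
    if (discordant[i]) {
      tr2 <- phangorn::rNNI(species_tree, moves = 1)
      if (is.null(tr2$edge.length))
        tr2$edge.length <- rep(mean(species_tree$edge.length),
                               nrow(tr2$edge))
      tr <- tr2
    }
    tr$edge.length <- tr$edge.length * rate_multipliers[i]
    trees[[i]] <- tr
  }
  attr(trees, "discordant") <- discordant
  attr(trees, "rate_multipliers") <- rate_multipliers
  trees
}

# ---- sequence simulation ----------------------------------------------------

# simulate states at all nodes; returns integer matrix (n_nodes x length)
sim_all_node_states <- function(tree, length, frequencies) {
  ed <- tree_preorder_edges(tree)
  ev <- edge_event_probs(ed$length, frequencies)
  sim_node_states_cpp(ed$parent, ed$child, ev, ed$n_nodes, ed$root,
                      frequencies, as.integer(length))
}

states_to_alignment <- function(states, tree, gene_id, states_chr = AA_RESIDUES,
                                alphabet = "aa") {
  m <- matrix(states_chr[states[seq_len(ape::Ntip(tree)), , drop = FALSE] + 1L],
              nrow = ape::Ntip(tree), dimnames = list(tree$tip.label, NULL))
  gene_alignment(gene_id, m, alphabet = alphabet)
}

#' Simulate an alignment on a tree
#'
#' Evolves each column independently down the tree under a frequency-driven
#' replacement process: over a branch of length `t` (expected replacements
#' per site) the transition probability is
#' `P(i -> j) = pi_j (1 - exp(-beta t)) + [i == j] exp(-beta t)` with
#' `beta = 1 / (1 - sum pi^2)`.  Root states are drawn from `frequencies`.
#' The process is stationary and compositionally homogeneous, which makes
#' it the null generator for the compositional homogeneity test.
#'
#' @param tree A `phylo` tree with non-negative branch lengths.
#' @param length Number of alignment columns.
#' @param frequencies Stationary 20-vector summing to 1 (order
#'   `ACDEFGHIKLMNPQRSTVWY`).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param gene_id Gene id for the result.
#' @return A [gene_alignment()] over the tree's tip labels.
#' @export
#' @examples
#' tr <- simulate_species_tree(6, seed = 1)
#' g <- simulate_alignment(tr, 100, protein_frequencies(), seed = 2)
simulate_alignment <- function(tree, length, frequencies = protein_frequencies(),
                               seed = NULL, gene_id = "sim") {
  check_frequencies(frequencies)
  if (!is.null(seed)) set.seed(seed)
  states <- sim_all_node_states(tree, length, frequencies)
  states_to_alignment(states, tree, gene_id)
}

#' Simulate an alignment with a compositional shift in selected taxa
#'
#' Identical to [simulate_alignment()] except that the terminal branches of
#' `shifted_taxa` evolve under the mixed stationary distribution
#' `(1 - s) * frequencies + s * disturbed_frequencies`: heterogeneity in
#' the stationary amino-acid frequencies among samples, the violation the
#' compositional homogeneity test is designed to catch.  With
#' `shift_strength = 0` the output is identical to the unshifted
#' simulation for the same seed.
#'
#' @inheritParams simulate_alignment
#' @param shifted_taxa Subset of the tree's tip labels.
#' @param shift_strength Mixing weight `s` in `[0, 1]`.
#' @param disturbed_frequencies Disturbed stationary 20-vector.
#' @return A [gene_alignment()].
#' @export
apply_compositional_shift <- function(tree, length,
                                      frequencies = protein_frequencies(),
                                      shifted_taxa, shift_strength,
                                      disturbed_frequencies = concentrated_frequencies("R"),
                                      seed = NULL, gene_id = "sim") {
  check_frequencies(frequencies)
  check_frequencies(disturbed_frequencies)
  if (shift_strength < 0 || shift_strength > 1)
    stop("shift_strength must be in [0, 1]")
  unknown <- setdiff(shifted_taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxon: ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  states <- sim_all_node_states(tree, length, frequencies)
  if (shift_strength > 0 && length(shifted_taxa)) {
    mixed <- (1 - shift_strength) * frequencies +
      shift_strength * disturbed_frequencies
    tips <- sort(match(shifted_taxa, tree$tip.label))
    for (tip in tips) {
      e <- which(tree$edge[, 2L] == tip)
      parent <- tree$edge[e, 1L]
      q <- edge_event_probs(tree$edge.length[e], mixed)
      hit <- runif(length) < q
      row <- states[parent, ]
      if (any(hit))
        row[hit] <- sample.int(20L, sum(hit), replace = TRUE, prob = mixed) - 1L
      states[tip, ] <- row
    }
  }
  states_to_alignment(states, tree, gene_id)
}

# ---- missingness ------------------------------------------------------------

#' Impose per-gene taxon occupancy on an ortholog set
#'
#' For each gene, exactly `occupancy_targets[i]` taxa retain their
#' sequences; the others are removed from the gene (absent records, not
#' gap-padded rows), mirroring how orthology inference reports partial
#' occupancy.
#'
#' @param set An [ortholog_set()].
#' @param occupancy_targets Integer scalar or per-gene vector of taxa to
#'   retain (each at least 1 and at most the gene's current row count).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param always_keep Optional character vector (or per-gene list) of
#'   terminals that must stay present in every gene they occur in.
#' @return An [ortholog_set()] with thinned genes.
#' @export
apply_missingness <- function(set, occupancy_targets, seed = NULL,
                              always_keep = NULL) {
  n <- length(set$genes)
  occupancy_targets <- rep_len(as.integer(occupancy_targets), n)
  if (any(occupancy_targets < 1)) stop("target < 1")
  if (any(occupancy_targets > nrow(set$manifest)))
    stop("occupancy target exceeds the number of manifest taxa")
  if (!is.null(seed)) set.seed(seed)
  keep_list <- if (is.list(always_keep)) rep_len(always_keep, n)
               else rep(list(always_keep), n)
  genes <- vector("list", n)
  for (i in seq_len(n)) {
    g <- set$genes[[i]]
    taxa <- aln_taxa(g)
    k <- occupancy_targets[i]
    if (k > length(taxa))
      stop("occupancy target ", k, " exceeds taxa of gene ", g$gene_id)
    forced <- intersect(keep_list[[i]], taxa)
    if (length(forced) > k) forced <- forced[seq_len(k)]
    pool <- setdiff(taxa, forced)
    extra <- sample(pool, k - length(forced))
    keep <- taxa[taxa %in% c(forced, extra)]     # preserve row order
    genes[[i]] <- gene_alignment(g$gene_id, g$aln[keep, , drop = FALSE],
                                 alphabet = g$alphabet)
  }
  replace_genes(set, genes)
}

# ---- whole-set simulation ---------------------------------------------------

#' Simulation configuration
#'
#' Bundles and validates the parameters of a full synthetic ortholog-set
#' simulation.
#'
#' @param n_taxa,n_genes,gene_length Positive integers; `gene_length` may
#'   be a per-gene vector.
#' @param rate_multipliers Per-gene positive rate multipliers (recycled).
#' @param base_frequencies Stationary 20-vector summing to 1 (tolerance
#'   1e-9).
#' @param shifted_taxa Terminals whose terminal branches get the
#'   compositional shift.
#' @param shift_strength Mixing weight in `[0, 1]`.
#' @param disturbed_frequencies Disturbed stationary 20-vector.
#' @param occupancy_targets Per-gene number of present taxa (recycled; must
#'   not exceed `n_taxa`).
#' @param discordance_prob Gene-tree discordance probability.
#' @param seed Integer seed for the whole simulation.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa, n_genes, gene_length,
                              rate_multipliers = 1,
                              base_frequencies = protein_frequencies(),
                              shifted_taxa = character(),
                              shift_strength = 0,
                              disturbed_frequencies = concentrated_frequencies("R"),
                              occupancy_targets = n_taxa,
                              discordance_prob = 0,
                              seed = 1L) {
  stopifnot(n_taxa >= 3, n_genes >= 1, all(gene_length >= 1))
  if (any(rate_multipliers <= 0)) stop("rate_multipliers must be positive")
  check_frequencies(base_frequencies)
  check_frequencies(disturbed_frequencies)
  if (shift_strength < 0 || shift_strength > 1)
    stop("shift_strength must be in [0, 1]")
  if (any(occupancy_targets > n_taxa))
    stop("occupancy_targets must not exceed n_taxa")
  if (any(occupancy_targets < 1)) stop("target < 1")
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 rate_multipliers = rate_multipliers,
                 base_frequencies = base_frequencies,
                 shifted_taxa = shifted_taxa,
                 shift_strength = shift_strength,
                 disturbed_frequencies = disturbed_frequencies,
                 occupancy_targets = as.integer(occupancy_targets),
                 discordance_prob = discordance_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a full ortholog set from a configuration
#'
#' Wires the generators together: species tree, discordant gene trees with
#' per-gene rate multipliers, per-gene alignments (with the compositional
#' shift where configured), then patterned missingness.
#'
#' @param config A [simulation_config()].
#' @param manifest Optional [taxon_manifest()]; by default a flat manifest
#'   labelled `"simulated"` is built over `t1 ... tn`.
#' @param shifted_genes Indices of genes that receive the compositional
#'   shift (default: all genes when `shift_strength > 0`).
#' @return List with elements `set` ([ortholog_set()]), `species_tree`,
#'   `gene_trees`.
#' @export
simulate_ortholog_set <- function(config, manifest = NULL,
                                  shifted_genes = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  labels <- if (is.null(manifest)) paste0("t", seq_len(config$n_taxa))
            else manifest$terminal_id
  if (is.null(manifest))
    manifest <- taxon_manifest(labels, rep("simulated", config$n_taxa),
                               rep("published_ingroup", config$n_taxa))
  sp <- simulate_species_tree(config$n_taxa, labels = labels)
  gt <- simulate_gene_trees(sp, config$n_genes, config$discordance_prob,
                            rate_multipliers = config$rate_multipliers)
  if (is.null(shifted_genes))
    shifted_genes <- if (config$shift_strength > 0) seq_len(config$n_genes)
                     else integer()
  lens <- rep_len(config$gene_length, config$n_genes)
  genes <- vector("list", config$n_genes)
  for (i in seq_len(config$n_genes)) {
    id <- sprintf("OG%06d", i)
    genes[[i]] <- if (i %in% shifted_genes)
      apply_compositional_shift(gt[[i]], lens[i], config$base_frequencies,
                                config$shifted_taxa, config$shift_strength,
                                config$disturbed_frequencies, gene_id = id)
    else
      simulate_alignment(gt[[i]], lens[i], config$base_frequencies,
                         gene_id = id)
  }
  set <- ortholog_set(manifest, genes)
  set <- apply_missingness(set, config$occupancy_targets,
                           always_keep = config$shifted_taxa)
  list(set = set, species_tree = sp, gene_trees = gt)
}
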