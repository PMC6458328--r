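# Tree-side utilities: Newick I/O with support normalization, bipartition
# algebra, Robinson-Foulds distances, neighbour joining, split-support
# congruence tables across analyses, posterior bipartition frequencies,
# the between-chain maxdiff convergence diagnostic, and rogue-terminal
# pruning from tree lists.

# ---- Newick I/O -------------------------------------------------------------

# minimal structural validation so malformed input fails with a position,
# not with whatever ape improvises
check_newick_text <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parentheses at position ", i)
    }
  }
  if (depth != 0L)
    stop("unbalanced parentheses: ", depth, " unclosed at end of string")
  invisible(text)
}

#' Parse / write Newick trees
#'
#' `parse_newick` accepts support values either as internal-node labels
#' (`((A,B)95,...)`) or as branch comments; numeric supports greater than 1
#' are taken as percentages and divided by 100, so bootstrap percentages
#' and posterior proportions end up on one `[0, 1]` scale.  Duplicate tip
#' labels and unbalanced parentheses are errors.  `write_newick` is the
#' inverse; `parse_newick(write_newick(t))` preserves topology, branch
#' lengths and supports.
#'
#' @param text A Newick string (or a path via [ape::read.tree()]
#'   semantics is *not* supported here: pass text).
#' @return `parse_newick` a `phylo`; `write_newick` a Newick string.
#' @export
#' @examples
#' tr <- parse_newick("((A,B)95,(C,D));")
#' tr$node.label
parse_newick <- function(text) {
  check_newick_text(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    big <- !is.na(sup) & sup > 1
    sup[big] <- sup[big] / 100          # percent -> proportion
    tr$node.label[!is.na(sup)] <- format(sup[!is.na(sup)], trim = TRUE,
                                         digits = 15)
  }
  tr
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Read / write Newick tree lists (one tree per line)
#'
#' @param path File with one Newick tree per line (e.g. a posterior tree
#'   sample).
#' @return `read_tree_list` a list of `phylo`; `write_tree_list` returns
#'   `path` invisibly.
#' @export
read_tree_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick)
}

#' @rdname read_tree_list
#' @param trees List of `phylo` objects.
#' @export
write_tree_list <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
  invisible(path)
}

# ---- bipartitions -----------------------------------------------------------

# canonical key of one side of a split: the side NOT containing the
# reference terminal (lexicographically smallest label of the full taxon
# set), labels sorted and comma-joined
canonical_split <- function(side, taxa) {
  ref <- min(taxa)
  if (ref %in% side) side <- setdiff(taxa, side)
  paste(sort(side), collapse = ",")
}

#' Internal bipartitions of a tree
#'
#' Returns the non-trivial splits (internal edges) of a tree, treated as
#' unrooted: the root edge is collapsed, so a binary tree over `n` taxa
#' yields exactly `n - 3` splits.  Each split is canonicalized by the side
#' not containing the reference terminal (the lexicographically smallest
#' tip label), making a split and its complement hash-equal.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split keys (sorted labels joined
#'   by commas), with the member labels as a `"sides"` attribute.
#' @export
#' @examples
#' bipartitions(parse_newick("(A,B,(C,(D,E)));"))
bipartitions <- function(tree) {
  split_supports(tree)$keys
}

# descendant tip labels of every node (tips and internal), by postorder
node_tipsets <- function(tr) {
  n <- ape::Ntip(tr)
  sets <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) sets[[i]] <- tr$tip.label[i]
  tr2 <- stats::reorder(tr, "postorder")
  for (e in seq_len(nrow(tr2$edge))) {
    p <- tr2$edge[e, 1L]
    sets[[p]] <- c(sets[[p]], sets[[tr2$edge[e, 2L]]])
  }
  sets
}

# splits of a tree together with their support values (node labels of the
# child node of each internal edge).  The tree is treated as unrooted: the
# root node itself is skipped, so for a rooted binary tree the two root
# children collapse onto one split (whichever of them carries a support
# label supplies it).
split_supports <- function(tree) {
  n <- ape::Ntip(tree)
  taxa <- tree$tip.label
  if (n < 4 || tree$Nnode <= 1)
    return(list(keys = character(), support = numeric()))
  sets <- node_tipsets(tree)
  root <- n + 1L
  keys <- character()
  support <- numeric()
  for (node in setdiff(seq.int(n + 1L, n + tree$Nnode), root)) {
    side <- sets[[node]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    sup <- NA_real_
    if (!is.null(tree$node.label)) {
      v <- suppressWarnings(as.numeric(tree$node.label[node - n]))
      if (!is.na(v)) sup <- if (v > 1) v / 100 else v
    }
    keys <- c(keys, canonical_split(side, taxa))
    support <- c(support, sup)
  }
  # a rooted tree repeats the root split on both root children; merge,
  # preferring a cell that actually carries a support value
  ord <- order(is.na(support))
  keys <- keys[ord]
  support <- support[ord]
  keep <- !duplicated(keys)
  list(keys = keys[keep], support = support[keep])
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the bipartition sets of two
#' trees over the same terminals.
#'
#' @param t1,t2 `phylo` objects with identical tip sets.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  d <- c(setdiff(t1$tip.label, t2$tip.label),
         setdiff(t2$tip.label, t1$tip.label))
  if (length(d))
    stop("terminal sets differ: ", paste(d, collapse = ", "))
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (via [ape::nj()]) with negative estimated
#' branch lengths truncated to zero.
#'
#' @param distances Symmetric numeric matrix with zero diagonal and
#'   labelled rows, `n >= 3`.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances) {
  distances <- as.matrix(distances)
  if (nrow(distances) < 3) stop("neighbour joining needs at least 3 taxa")
  if (any(is.na(distances)) || any(is.nan(distances)))
    stop("distances contain NA/NaN")
  if (any(distances < 0)) stop("distances contain negative values")
  if (any(abs(diag(distances)) > 1e-12)) stop("diagonal must be zero")
  if (max(abs(distances - t(distances))) > 1e-8)
    stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(distances))
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# ---- congruence across analyses --------------------------------------------

#' Split-support congruence table
#'
#' For each internal bipartition of a reference tree, collects the support
#' that every analysis assigns to the matching split, or `NA` when the
#' split is absent from that analysis (the "grey square" case).  A summary
#' column flags splits on which all analyses agree with full support.
#'
#' @param reference A `phylo` tree whose internal splits define the rows.
#' @param analyses Named list of `phylo` trees (names become columns).
#'   All trees must share the reference terminal set; mismatches are an
#'   error, not silently pruned.
#' @return A `data.frame` of class `split_support_table`: column `split`
#'   (canonical key), one numeric column per analysis (support in
#'   `[0, 1]`, `NA` = absent) and logical `all_full`.
#' @export
split_support_table <- function(reference, analyses) {
  if (is.null(names(analyses)) || any(!nzchar(names(analyses))))
    stop("analyses must be a named list")
  ref_taxa <- sort(reference$tip.label)
  for (nm in names(analyses)) {
    d <- c(setdiff(ref_taxa, analyses[[nm]]$tip.label),
           setdiff(analyses[[nm]]$tip.label, ref_taxa))
    if (length(d))
      stop("terminal set of analysis '", nm, "' differs from the reference: ",
           paste(d, collapse = ", "))
  }
  rows <- bipartitions(reference)
  out <- data.frame(split = rows, stringsAsFactors = FALSE)
  for (nm in names(analyses)) {
    ss <- split_supports(analyses[[nm]])
    out[[nm]] <- ss$support[match(rows, ss$keys)]
  }
  sup <- as.matrix(out[, names(analyses), drop = FALSE])
  out$all_full <- apply(sup, 1L, function(v) all(!is.na(v) & v >= 1))
  class(out) <- c("split_support_table", "data.frame")
  out
}

#' Write a split-support table as TSV
#'
#' Splits are written in the canonical `"A|B"` form (both sides, sorted);
#' absent splits are written as `NA`.
#'
#' @param table A [split_support_table()].
#' @param taxa Full taxon set (character), used to print both sides of
#'   each split.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split_support_tsv <- function(table, taxa, path) {
  d <- as.data.frame(table)
  side1 <- strsplit(d$split, ",")
  d$split <- vapply(side1, function(s)
    paste(paste(s, collapse = ","), paste(sort(setdiff(taxa, s)), collapse = ","),
          sep = "|"), character(1))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- posterior samples and convergence --------------------------------------

check_shared_taxa <- function(trees) {
  taxa <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), taxa))
      stop("tree ", i, " has a different terminal set")
  }
  taxa
}

#' Bipartition frequencies of a tree sample
#'
#' Frequency of every split observed in at least one tree of the list:
#' (number of trees containing the split) / (number of trees).
#'
#' @param treelist Non-empty list of `phylo` trees over one taxon set.
#' @param burnin Fraction of leading trees to discard (default 0).
#' @return Named numeric vector (canonical split key -> frequency in
#'   `(0, 1]`).
#' @export
bipartition_frequencies <- function(treelist, burnin = 0) {
  if (!length(treelist)) stop("empty tree list")
  if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
  if (burnin > 0)
    treelist <- treelist[-seq_len(floor(burnin * length(treelist)))]
  check_shared_taxa(treelist)
  splits <- unlist(lapply(treelist, bipartitions))
  if (!length(splits)) return(setNames(numeric(), character()))
  tab <- table(splits)
  setNames(as.numeric(tab) / length(treelist), names(tab))
}

#' Between-chain maxdiff convergence diagnostic
#'
#' The maximum absolute difference in bipartition frequencies between two
#' tree samples, taken over the union of splits observed in either chain
#' (a split absent from a chain has frequency 0).  Values near 0 indicate
#' topological convergence; a chain-fixed rogue terminal alone drives
#' maxdiff to 1.
#'
#' @param chain_a,chain_b Non-empty lists of `phylo` trees over one taxon
#'   set.
#' @param burnin Fraction of leading trees discarded from each chain.
#' @return A value in `[0, 1]`.
#' @export
maxdiff <- function(chain_a, chain_b, burnin = 0) {
  fa <- bipartition_frequencies(chain_a, burnin = burnin)
  fb <- bipartition_frequencies(chain_b, burnin = burnin)
  if (!identical(sort(check_shared_taxa(chain_a)),
                 sort(check_shared_taxa(chain_b))))
    stop("the two chains have different terminal sets")
  keys <- union(names(fa), names(fb))
  if (!length(keys)) return(0)
  a <- ifelse(keys %in% names(fa), fa[keys], 0)
  b <- ifelse(keys %in% names(fb), fb[keys], 0)
  max(abs(a - b))
}

#' Prune a terminal from every tree of a list
#'
#' Removes the taxon, suppresses the resulting degree-2 nodes and sums the
#' merged branch lengths, so path lengths among the remaining terminals
#' are preserved.  The tree count is unchanged.  Used to excise rogue
#' terminals whose unstable placement masks otherwise converged chains.
#'
#' @param treelist List of `phylo` trees.
#' @param taxon Terminal label present in every tree.
#' @return List of pruned `phylo` trees.
#' @export
prune_terminal <- function(treelist, taxon) {
  for (i in seq_along(treelist)) {
    if (!taxon %in% treelist[[i]]$tip.label)
      stop("taxon '", taxon, "' absent from tree ", i)
  }
  lapply(treelist, function(tr) ape::drop.tip(tr, taxon))
}
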