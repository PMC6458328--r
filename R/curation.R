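# Supermatrix curation: occupancy accounting and slicing, alignment end
# trimming, rate-proxy computation and rate-tail removal, concatenation
# with partition bookkeeping, outgroup-restricted subsetting, and
# longest-isoform selection.

#' Default curation thresholds
#'
#' The thresholds of the four-matrix construction protocol: the base
#' occupancy slice (50%), the high-occupancy slice (70%), the rate tails
#' removed from each end of the gene-rate ranking (20%), the maximum
#' missingness tolerated in terminal alignment columns (80%) and the
#' significance level of the compositional homogeneity filter (0.1).
#'
#' @return Named list of numeric fractions, all in `[0, 1]`.
#' @export
curation_config <- function() {
  list(occupancy_fraction_m1 = 0.5,
       occupancy_fraction_m4 = 0.7,
       rate_tail_fraction = 0.2,
       end_trim_max_missing = 0.8,
       composition_alpha = 0.1)
}

#' Gene-by-taxon occupancy of an ortholog set
#'
#' A terminal counts as present for a gene when it has a sequence record
#' containing at least one residue; all-gap (or all-`X`) rows count as
#' absent.
#'
#' @param set An [ortholog_set()].
#' @return List of class `occupancy_matrix`: `presence` (logical gene x
#'   taxon matrix over the manifest), `gene_counts` (per-gene present-taxon
#'   counts) and `taxon_counts` (per-taxon gene counts).
#' @export
compute_occupancy <- function(set) {
  if (length(set$genes) == 0L) stop("empty ortholog set")
  taxa <- set$manifest$terminal_id
  presence <- matrix(FALSE, length(set$genes), length(taxa),
                     dimnames = list(gene_ids(set), taxa))
  for (i in seq_along(set$genes)) {
    g <- set$genes[[i]]
    has_res <- rowSums(residue_mask(g)) > 0
    presence[i, aln_taxa(g)[has_res]] <- TRUE
  }
  structure(list(presence = presence,
                 gene_counts = rowSums(presence),
                 taxon_counts = colSums(presence)),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat("Occupancy:", nrow(x$presence), "genes x", ncol(x$presence),
      "taxa; mean per-gene occupancy",
      round(mean(x$gene_counts) / ncol(x$presence), 3), "\n")
  invisible(x)
}

#' Write an occupancy table as TSV
#'
#' @param occ An `occupancy_matrix` from [compute_occupancy()].
#' @param path Output file; genes and taxa are sorted best-sampled first.
#' @return `path`, invisibly.
#' @export
write_occupancy_tsv <- function(occ, path) {
  p <- occ$presence[order(occ$gene_counts, decreasing = TRUE),
                    order(occ$taxon_counts, decreasing = TRUE), drop = FALSE]
  d <- data.frame(gene_id = rownames(p), present = rowSums(p), p * 1L,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Slice an ortholog set by taxon occupancy
#'
#' Keeps genes for which at least `ceiling(fraction * n_taxa)` manifest
#' terminals are present ("at least half of the terminals" at 0.5).  Input
#' gene order is preserved; the operation is idempotent.
#'
#' @param set An [ortholog_set()].
#' @param fraction Occupancy fraction in `[0, 1]`.
#' @return The filtered [ortholog_set()].
#' @export
#' @examples
#' cfg <- curation_config()
#' cfg$occupancy_fraction_m4  # the high-occupancy slice
slice_by_occupancy <- function(set, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (length(set$genes) == 0L) return(set)
  threshold <- ceiling(fraction * nrow(set$manifest))
  occ <- compute_occupancy(set)
  replace_genes(set, set$genes[occ$gene_counts >= threshold])
}

#' Trim ragged alignment ends
#'
#' Removes columns from the left end while the column's missingness
#' (fraction of `'-'` or `'X'` over the taxa present in the gene) exceeds
#' `max_missing`, then the same from the right end.  Interior columns are
#' never touched, so a fully gapped column flanked by clean columns
#' survives.  The result can be empty.
#'
#' @param gene A [gene_alignment()].
#' @param max_missing Maximum tolerated missingness of a terminal column.
#' @return The trimmed [gene_alignment()].
#' @export
trim_ends <- function(gene, max_missing = 0.8) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]")
  miss <- 1 - colMeans(residue_mask(gene))
  n <- length(miss)
  left <- 0L
  while (left < n && miss[left + 1L] > max_missing) left <- left + 1L
  right <- n + 1L
  while (right > left + 1L && miss[right - 1L] > max_missing) right <- right - 1L
  keep <- if (left + 1L > right - 1L) integer() else seq.int(left + 1L, right - 1L)
  gene_alignment(gene$gene_id, gene$aln[, keep, drop = FALSE],
                 alphabet = gene$alphabet)
}

#' Evolutionary-rate proxy of a gene
#'
#' Mean over unordered sequence pairs of the p-distance (proportion of
#' mismatched residues over mutually ungapped columns).  A transparent,
#' order-preserving proxy for the relative evolutionary rate of a gene;
#' pairs with no comparable column are skipped.
#'
#' @param gene A [gene_alignment()] with at least 2 sequences.
#' @return Mean pairwise p-distance in `[0, 1]`.
#' @export
#' @examples
#' gene_rate(gene_alignment("g", c(a = "ACDE", b = "ACDF")))  # 0.25
gene_rate <- function(gene) {
  if (nrow(gene$aln) < 2) stop("gene_rate needs at least 2 sequences")
  p <- pdistance_matrix(gene)
  vals <- p[upper.tri(p)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("rate undefined: no comparable sequence pair")
  mean(vals)
}

#' Rate proxies for every gene of a set
#'
#' @param set An [ortholog_set()].
#' @return Named numeric vector of [gene_rate()] values.
#' @export
gene_rates <- function(set) {
  vapply(set$genes, gene_rate, numeric(1))
}

#' Remove the slowest and fastest evolving genes
#'
#' Ranks genes by rate ascending (ties broken by gene id) and removes the
#' `ceiling(lower_fraction * n)` slowest and `ceiling(upper_fraction * n)`
#' fastest; this tail convention takes 1059 genes to 635 at 20%/20%.
#' Original gene order is preserved among survivors.
#'
#' @param set An [ortholog_set()].
#' @param lower_fraction,upper_fraction Tail fractions; their sum must be
#'   below 1.
#' @param rates Optional precomputed named rate vector (defaults to
#'   [gene_rates()]); must cover every gene.
#' @return The filtered [ortholog_set()] with attribute `"removed"` naming
#'   the dropped genes.
#' @export
remove_rate_tails <- function(set, lower_fraction, upper_fraction,
                              rates = NULL) {
  if (lower_fraction < 0 || upper_fraction < 0 ||
      lower_fraction + upper_fraction >= 1)
    stop("tail fractions must be non-negative and sum below 1")
  ids <- gene_ids(set)
  if (is.null(rates)) rates <- gene_rates(set)
  if (!all(ids %in% names(rates))) stop("rates must cover every gene")
  rates <- rates[ids]
  n <- length(ids)
  ord <- ids[order(rates, ids)]            # ascending, ties by gene_id
  n_low <- ceiling(lower_fraction * n)
  n_high <- ceiling(upper_fraction * n)
  drop <- c(head(ord, n_low), tail(ord, n_high))
  keep <- setdiff(ids, drop)
  out <- replace_genes(set, set$genes[ids %in% keep])
  attr(out, "removed") <- drop
  out
}

#' Concatenate an ortholog set into a supermatrix
#'
#' Every manifest terminal gets a row of the total length; terminals
#' missing a gene are filled with `'?'` over that gene's columns
#' (conventional for absent data, versus `'-'` for indels).  Partition
#' coordinates are 1-based inclusive, in input gene order.
#'
#' @param set A non-empty [ortholog_set()].
#' @return Object of class `supermatrix`: list with `rows` (named character
#'   vector) and `partitions` (`data.frame` with `gene_id`, `start`,
#'   `end`).
#' @export
concatenate <- function(set) {
  if (length(set$genes) == 0L) stop("cannot concatenate an empty set")
  taxa <- set$manifest$terminal_id
  lens <- vapply(set$genes, aln_length, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  pieces <- matrix("", length(taxa), length(set$genes),
                   dimnames = list(taxa, NULL))
  for (i in seq_along(set$genes)) {
    g <- set$genes[[i]]
    if (anyDuplicated(aln_taxa(g)))
      stop("duplicate terminal within gene ", g$gene_id)
    s <- aln_strings(g)
    fill <- strrep("?", lens[i])
    pieces[, i] <- ifelse(taxa %in% names(s), s[taxa], fill)
  }
  rows <- setNames(apply(pieces, 1L, paste, collapse = ""), taxa)
  structure(list(rows = rows,
                 partitions = data.frame(gene_id = gene_ids(set),
                                         start = starts, end = ends,
                                         row.names = NULL)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$rows), "terminals x",
      if (nrow(x$partitions)) max(x$partitions$end) else 0L, "columns,",
      nrow(x$partitions), "partitions\n")
  invisible(x)
}

#' Write a supermatrix and its partitions
#'
#' `write_supermatrix_fasta` writes plain FASTA;
#' `write_supermatrix_phylip` writes relaxed PHYLIP (name, space,
#' sequence); `write_partition_file` writes RAxML-style lines
#' `MODEL, gene = start-end` with 1-based inclusive coordinates.
#'
#' @param sm A `supermatrix` from [concatenate()].
#' @param path Output file.
#' @param model Substitution-model tag for the partition file.
#' @return `path`, invisibly.
#' @export
write_supermatrix_fasta <- function(sm, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(sm$rows), path)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_supermatrix_phylip <- function(sm, path) {
  n <- length(sm$rows)
  len <- if (n) nchar(sm$rows[[1]]) else 0L
  writeLines(c(paste(n, len),
               paste(names(sm$rows), sm$rows)), path)
  invisible(path)
}

#' @rdname write_supermatrix_fasta
#' @export
write_partition_file <- function(sm, path, model = "LG") {
  writeLines(sprintf("%s, %s = %d-%d", model, sm$partitions$gene_id,
                     sm$partitions$start, sm$partitions$end), path)
  invisible(path)
}

#' Restrict an ortholog set to the ingroup plus one outgroup class
#'
#' Retains all ingroup terminals (source classes `new` and
#' `published_ingroup`) plus the outgroup terminals whose `group_label`
#' equals `keep_group`.  The gene list is unchanged: genes are not
#' re-sliced against occupancy, matching the construction of
#' outgroup-test datasets from the largest matrix.
#'
#' @param set An [ortholog_set()].
#' @param keep_group A `group_label` present in the manifest.
#' @return The restricted [ortholog_set()] (manifest and gene rows
#'   filtered, gene list identical).
#' @export
subset_outgroups <- function(set, keep_group) {
  man <- set$manifest
  if (!keep_group %in% man$group_label)
    stop("unknown group '", keep_group, "'; available: ",
         paste(sort(unique(man$group_label)), collapse = ", "))
  keep <- man$source_class != "outgroup" | man$group_label == keep_group
  man2 <- man[keep, , drop = FALSE]
  class(man2) <- class(man)
  genes <- lapply(set$genes, function(g) {
    rows <- intersect(aln_taxa(g), man2$terminal_id)
    gene_alignment(g$gene_id, g$aln[rows, , drop = FALSE],
                   alphabet = g$alphabet)
  })
  ortholog_set(man2, genes)
}

#' Keep the longest isoform per gene
#'
#' Collapses assembler isoforms to one sequence per gene key.  The gene key
#' is the sequence id with a single trailing isoform token removed
#' (pattern `[._](i|p)?[0-9]+$`, covering ids such as
#' `TRINITY_DN1000_c0_g1_i2` or `gene12.3`); ids without such a token are
#' passed through as their own key with a message.  The longest sequence
#' wins; ties go to the lexicographically smallest sequence id.
#'
#' @param peptides Named character vector (names = sequence ids) or a
#'   `data.frame` with columns `sequence_id`, `sequence`.
#' @return `data.frame` with columns `gene_key`, `sequence_id`,
#'   `sequence`, one row per gene key, ordered by gene key.
#' @export
select_longest_isoform <- function(peptides) {
  if (is.data.frame(peptides)) {
    ids <- as.character(peptides$sequence_id)
    seqs <- as.character(peptides$sequence)
  } else {
    ids <- names(peptides)
    seqs <- as.character(peptides)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("sequence ids are required")
  pattern <- "[._](i|p)?[0-9]+$"
  has_token <- grepl(pattern, ids)
  if (any(!has_token))
    message("no isoform token in ", sum(!has_token),
            " id(s); passed through as their own gene key")
  key <- ifelse(has_token, sub(pattern, "", ids), ids)
  d <- data.frame(gene_key = key, sequence_id = ids, sequence = seqs,
                  len = nchar(seqs), stringsAsFactors = FALSE)
  d <- d[order(d$gene_key, -d$len, d$sequence_id), ]
  d <- d[!duplicated(d$gene_key), c("gene_key", "sequence_id", "sequence")]
  rownames(d) <- NULL
  d
}
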