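#' Create a gene (orthogroup) alignment
#'
#' One orthogroup's aligned sequences keyed by terminal.  Rows must be equal
#' length; characters are restricted to the declared alphabet plus the gap
#' `'-'` and unknown `'X'` symbols.  Taxa with no sequence for the gene are
#' simply absent (no gap-padded rows), which is how orthology pipelines
#' report partial occupancy.
#'
#' @param gene_id Single non-empty string.
#' @param seqs Named character vector of aligned sequences (one string per
#'   terminal), or a character matrix with one row per terminal and one
#'   aligned column per matrix column (rownames = terminal ids).
#' @param alphabet `"aa"` (20 residues) or `"dayhoff6"` (digits 1-6).
#' @return An object of class `gene_alignment`: a list with elements
#'   `gene_id`, `aln` (character matrix, taxa x columns) and `alphabet`.
#' @export
#' @examples
#' g <- gene_alignment("og1", c(A = "ACDE", B = "AC-E"))
#' aln_length(g)
gene_alignment <- function(gene_id, seqs, alphabet = "aa") {
  if (length(gene_id) != 1L || !nzchar(gene_id)) stop("gene_id must be a single non-empty string")
  states <- alphabet_states(alphabet)
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("sequences must be named by terminal_id")
    nc <- unique(nchar(seqs))
    if (length(nc) > 1L) stop("all rows must have equal length in gene ", gene_id)
    m <- matrix("", nrow = length(seqs), ncol = if (length(nc)) nc else 0L,
                dimnames = list(names(seqs), NULL))
    for (i in seq_along(seqs)) m[i, ] <- strsplit(seqs[[i]], "")[[1]]
  }
  if (is.null(rownames(m))) stop("alignment matrix needs terminal_id rownames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate terminal within gene ", gene_id, ": ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  bad <- !(m %in% c(states, "-", "X"))
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid character '", m[i], "' at row ",
         rownames(m)[(i - 1L) %% nrow(m) + 1L], ", column ",
         (i - 1L) %/% nrow(m) + 1L, " of gene ", gene_id)
  }
  structure(list(gene_id = gene_id, aln = m, alphabet = alphabet),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("Gene alignment", x$gene_id, ":", nrow(x$aln), "taxa x",
      ncol(x$aln), "columns (", x$alphabet, ")\n")
  invisible(x)
}

#' Alignment accessors
#'
#' @param gene A [gene_alignment()].
#' @return `aln_length` the number of columns; `aln_taxa` the terminal ids;
#'   `aln_strings` the rows collapsed back to named strings.
#' @export
aln_length <- function(gene) ncol(gene$aln)

#' @rdname aln_length
#' @export
aln_taxa <- function(gene) rownames(gene$aln)

#' @rdname aln_length
#' @export
aln_strings <- function(gene) {
  setNames(apply(gene$aln, 1L, paste, collapse = ""), rownames(gene$aln))
}

# logical matrix: TRUE where the character is an actual state (not '-'/'X')
residue_mask <- function(gene) {
  matrix(!(gene$aln %in% c("-", "X")), nrow = nrow(gene$aln),
         dimnames = dimnames(gene$aln))
}

#' Create an ortholog set
#'
#' A collection of gene alignments over a shared taxon manifest.  Every row
#' of every gene must name a manifest terminal, and gene ids must be unique.
#'
#' @param manifest A [taxon_manifest()].
#' @param genes List of [gene_alignment()] objects (order is preserved by
#'   all curation operations).
#' @return An object of class `ortholog_set` with elements `manifest` and
#'   `genes` (named by gene id).
#' @export
ortholog_set <- function(manifest, genes) {
  stopifnot(inherits(manifest, "taxon_manifest"))
  if (!all(vapply(genes, inherits, logical(1), "gene_alignment")))
    stop("genes must be gene_alignment objects")
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate gene_ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (g in genes) {
    extra <- setdiff(aln_taxa(g), manifest$terminal_id)
    if (length(extra))
      stop("gene ", g$gene_id, " has terminals not in the manifest: ",
           paste(extra, collapse = ", "))
  }
  names(genes) <- ids
  structure(list(manifest = manifest, genes = genes), class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("Ortholog set:", length(x$genes), "genes over",
      nrow(x$manifest), "terminals\n")
  invisible(x)
}

#' @export
length.ortholog_set <- function(x) length(x$genes)

#' Gene ids of an ortholog set
#' @param set An [ortholog_set()].
#' @return Character vector of gene ids in stored order.
#' @export
gene_ids <- function(set) names(set$genes)

# rebuild a set keeping validation but skipping re-checks for internal use
replace_genes <- function(set, genes) {
  names(genes) <- vapply(genes, function(g) g$gene_id, character(1))
  structure(list(manifest = set$manifest, genes = genes),
            class = "ortholog_set")
}

#' Read / write a gene alignment as FASTA
#'
#' Headers are terminal ids.  Reading goes through
#' [Biostrings::readBStringSet()] so any single-letter alphabet (amino
#' acids or Dayhoff digits) is accepted; writing emits plain wrapped FASTA.
#'
#' @param path FASTA file path.
#' @param gene_id Gene id to attach; defaults to the file base name.
#' @param alphabet `"aa"` or `"dayhoff6"`.
#' @return `read_gene_fasta` a [gene_alignment()]; `write_gene_fasta`
#'   returns `path` invisibly.
#' @export
read_gene_fasta <- function(path, gene_id = NULL, alphabet = "aa") {
  if (is.null(gene_id))
    gene_id <- sub("\\.(fa|fasta|faa)$", "", basename(path))
  x <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  gene_alignment(gene_id, toupper(seqs), alphabet = alphabet)
}

#' @rdname read_gene_fasta
#' @param gene A [gene_alignment()].
#' @export
write_gene_fasta <- function(gene, path) {
  s <- aln_strings(gene)
  Biostrings::writeXStringSet(Biostrings::BStringSet(s), path)
  invisible(path)
}

#' Write every gene of a set as one FASTA per orthogroup
#'
#' @param set An [ortholog_set()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_ortholog_fastas <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(gene_ids(set), ".fasta"))
  for (i in seq_along(set$genes)) write_gene_fasta(set$genes[[i]], paths[i])
  invisible(paths)
}

#' Read a directory of per-gene FASTA files into an ortholog set
#'
#' @param dir Directory containing `*.fasta`/`*.fa` files.
#' @param manifest A [taxon_manifest()] covering all terminals that occur.
#' @param alphabet Alignment alphabet.
#' @return An [ortholog_set()] with genes in file-name order.
#' @export
read_ortholog_fastas <- function(dir, manifest, alphabet = "aa") {
  files <- sort(list.files(dir, pattern = "\\.(fa|fasta|faa)$", full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", dir)
  ortholog_set(manifest, lapply(files, read_gene_fasta, alphabet = alphabet))
}

#' Pairwise p-distance matrix of a gene alignment
#'
#' p-distance between two rows is the proportion of mismatched states over
#' the columns where both rows carry a state (gaps and `X` excluded).
#' Pairs with no mutually ungapped column get `NA`.
#'
#' @param gene A [gene_alignment()].
#' @return Symmetric numeric matrix (taxa x taxa) with zero diagonal, plus
#'   an attribute `"comparable"` holding the per-pair count of comparable
#'   columns.
#' @export
pdistance_matrix <- function(gene) {
  ok <- residue_mask(gene)
  states <- alphabet_states(gene$alphabet)
  comp <- tcrossprod(ok * 1)                      # comparable columns / pair
  match <- matrix(0, nrow(comp), ncol(comp))
  for (r in states) {
    ind <- (gene$aln == r & ok) * 1
    match <- match + tcrossprod(ind)
  }
  p <- 1 - match / comp
  p[comp == 0] <- NA_real_
  diag(p) <- 0
  dimnames(p) <- list(aln_taxa(gene), aln_taxa(gene))
  attr(p, "comparable") <- comp
  p
}
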