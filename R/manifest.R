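#' Create a taxon manifest
#'
#' The manifest is the master list of terminals behind an ortholog set: one
#' row per terminal with its higher-level group (e.g. "Patellogastropoda",
#' "Bivalvia") and how it entered the study (`new`, `published_ingroup` or
#' `outgroup`).  Occupancy fractions are always computed against the
#' manifest, not against whichever taxa happen to occur in a gene.
#'
#' @param terminal_id Character vector of unique, non-empty terminal labels.
#' @param group_label Character vector of group labels, one per terminal.
#' @param source_class Character vector, each one of `"new"`,
#'   `"published_ingroup"` or `"outgroup"`.
#' @return A `data.frame` of class `taxon_manifest` with columns
#'   `terminal_id`, `group_label`, `source_class`.
#' @export
#' @examples
#' taxon_manifest(c("Lottia", "Mytilus"), c("Patellogastropoda", "Bivalvia"),
#'                c("published_ingroup", "outgroup"))
taxon_manifest <- function(terminal_id, group_label, source_class) {
  terminal_id <- as.character(terminal_id)
  group_label <- as.character(group_label)
  source_class <- as.character(source_class)
  if (length(terminal_id) == 0L) stop("manifest needs at least one terminal")
  if (anyDuplicated(terminal_id)) stop("terminal_ids must be unique")
  if (any(!nzchar(terminal_id))) stop("terminal_ids must be non-empty")
  if (length(group_label) != length(terminal_id) ||
      length(source_class) != length(terminal_id))
    stop("group_label and source_class must match terminal_id in length")
  if (any(!nzchar(group_label))) stop("every terminal needs a group_label")
  ok <- source_class %in% c("new", "published_ingroup", "outgroup")
  if (!all(ok))
    stop("invalid source_class: ", paste(unique(source_class[!ok]), collapse = ", "))
  out <- data.frame(terminal_id = terminal_id, group_label = group_label,
                    source_class = source_class, stringsAsFactors = FALSE)
  class(out) <- c("taxon_manifest", "data.frame")
  out
}

#' @export
print.taxon_manifest <- function(x, ...) {
  cat("Taxon manifest:", nrow(x), "terminals (",
      sum(x$source_class == "new"), "new,",
      sum(x$source_class == "published_ingroup"), "published ingroup,",
      sum(x$source_class == "outgroup"), "outgroup )\n")
  print(table(x$group_label))
  invisible(x)
}

#' Read / write a taxon manifest as TSV
#'
#' Plain three-column tab-separated text with a header line
#' `terminal_id  group_label  source_class`.
#'
#' @param path File path.
#' @return `read_taxon_manifest` returns a [taxon_manifest()];
#'   `write_taxon_manifest` returns `path` invisibly.
#' @export
read_taxon_manifest <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("terminal_id", "group_label", "source_class")
  if (!all(need %in% names(d)))
    stop("manifest TSV must have columns: ", paste(need, collapse = ", "))
  taxon_manifest(d$terminal_id, d$group_label, d$source_class)
}

#' @rdname read_taxon_manifest
#' @param manifest A [taxon_manifest()].
#' @export
write_taxon_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# terminals counted as ingroup (everything not an outgroup)
ingroup_ids <- function(manifest) {
  manifest$terminal_id[manifest$source_class != "outgroup"]
}
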