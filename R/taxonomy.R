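#' The fixed taxonomic rank ladder
#'
#' Lineages in this package run over six ranks, phylum through species.
#' Domain/kingdom are deliberately absent: queries whose database hits
#' conflict already at phylum are labelled `"unknown-eukaryotic"` rather
#' than being resolved at a rank above phylum.
#'
#' @return Character vector of the six ranks, deepest last.
#' @export
tax_ranks <- function() {
  c("phylum", "class", "order", "family", "genus", "species")
}

#' Construct a taxonomic path
#'
#' A `taxon_path` is a named character vector over the rank ladder of
#' [tax_ranks()], possibly truncated at any depth, with no internal gaps:
#' a path that names an order must also name the class and phylum above it.
#'
#' @param ... Either a single character vector of rank names (deepest last),
#'   or individual rank names. Unnamed input is assigned ranks in ladder
#'   order starting at phylum.
#' @return A `taxon_path` object.
#' @examples
#' taxon_path("Arthropoda", "Insecta", "Diptera", "Culicidae", "Aedes", "Aedes aegypti")
#' taxon_path("Mollusca")  # truncated at phylum
#' @export
taxon_path <- function(...) {
  x <- c(...)
  if (is.null(x) || length(x) == 0L) {
    p <- character(0)
    class(p) <- "taxon_path"
    return(p)
  }
  x <- as.character(x)
  ranks <- tax_ranks()
  if (length(x) > length(ranks))
    stop_format("taxon path deeper than the %d-rank ladder", length(ranks))
  if (any(!nzchar(x)) || anyNA(x))
    stop_format("taxon path names must be non-empty")
  names(x) <- ranks[seq_along(x)]
  class(x) <- "taxon_path"
  x
}

#' @export
print.taxon_path <- function(x, ...) {
  if (length(x) == 0L) cat("<empty taxon_path>\n")
  else cat(paste(unclass(x), collapse = "; "), "\n")
  invisible(x)
}

#' Deepest rank of a taxon path
#' @param path A `taxon_path`.
#' @return The deepest rank name present, or `NA` for an empty path.
#' @export
path_depth_rank <- function(path) {
  if (length(path) == 0L) return(NA_character_)
  tax_ranks()[length(path)]
}

# Rank index (1 = phylum ... 6 = species); NA input -> 0.
rank_index <- function(rank) {
  if (is.na(rank)) return(0L)
  match(rank, tax_ranks())
}

#' Read a taxonomy table
#'
#' Tab-separated, seven columns: a sequence identifier followed by the six
#' ranks of [tax_ranks()]. Empty cells are permitted only as a suffix
#' (a truncated lineage); a gap inside a lineage is a format error.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping id to [taxon_path()].
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    cells <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    # trailing empty fields may be dropped by strsplit; pad back to 7
    cells <- c(cells, rep("", 7L - length(cells)))
    if (length(cells) > 7L)
      stop_format("taxonomy row has more than 7 columns: %s", ln)
    id <- cells[1]
    if (!nzchar(id)) stop_format("taxonomy row with empty id")
    ranks <- cells[-1]
    filled <- nzchar(ranks)
    depth <- if (any(filled)) max(which(filled)) else 0L
    if (depth > 0L && !all(filled[seq_len(depth)]))
      stop_format("gap in lineage for '%s': ranks must truncate only as a suffix", id)
    if (id %in% names(out)) stop_format("duplicate taxonomy id '%s'", id)
    out[[id]] <- taxon_path(ranks[seq_len(depth)])
  }
  out
}

#' Write a taxonomy table
#'
#' @param taxonomy Named list of [taxon_path()] objects.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lines <- vapply(names(taxonomy), function(id) {
    p <- taxonomy[[id]]
    cells <- c(unclass(p), rep("", 6L - length(p)))
    paste(c(id, cells), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
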