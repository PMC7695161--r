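#' Taxonomy-annotated reference database
#'
#' Couples a set of reference barcode sequences with one full six-rank
#' lineage per sequence. This is the in-silico stand-in for a curated local
#' COI database: it serves both as the subject set for taxonomic searches
#' and as the template pool for the mock-community simulator.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param taxonomy Named list of [taxon_path()] objects, one per sequence id.
#' @return A `ref_db` object (list with elements `seqs` and `taxonomy`).
#' @export
ref_db <- function(seqs, taxonomy) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_format("reference sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop_format("duplicate reference id")
  missing <- setdiff(names(seqs), names(taxonomy))
  if (length(missing))
    stop_format("missing taxonomy for reference id(s): %s",
                paste(head(missing, 5L), collapse = ", "))
  obj <- list(seqs = setNames(toupper(as.character(seqs)), names(seqs)),
              taxonomy = taxonomy[names(seqs)])
  class(obj) <- "ref_db"
  obj
}

#' @export
print.ref_db <- function(x, ...) {
  cat(sprintf("ref_db: %d references, %d--%d bp\n", length(x$seqs),
              if (length(x$seqs)) min(nchar(x$seqs)) else 0L,
              if (length(x$seqs)) max(nchar(x$seqs)) else 0L))
  invisible(x)
}

#' @export
length.ref_db <- function(x) length(x$seqs)

#' Read / write a reference database
#'
#' A reference database on disk is a FASTA file plus a taxonomy TSV sharing
#' the same identifiers (see [read_taxonomy()]).
#'
#' @param fasta_path FASTA path.
#' @param taxonomy_path Taxonomy TSV path.
#' @param db A `ref_db` object (for writing).
#' @return `read_ref_db()` returns a `ref_db`.
#' @export
read_ref_db <- function(fasta_path, taxonomy_path) {
  ref_db(read_fasta(fasta_path), read_taxonomy(taxonomy_path))
}

#' @rdname read_ref_db
#' @export
write_ref_db <- function(db, fasta_path, taxonomy_path) {
  stopifnot(inherits(db, "ref_db"))
  write_fasta(db$seqs, fasta_path)
  write_taxonomy(db$taxonomy, taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

# Lineage matrix (rows = refs, cols = ranks, NA where truncated).
lineage_matrix <- function(taxonomy) {
  ranks <- tax_ranks()
  mat <- matrix(NA_character_, nrow = length(taxonomy), ncol = length(ranks),
                dimnames = list(names(taxonomy), ranks))
  for (i in seq_along(taxonomy)) {
    p <- taxonomy[[i]]
    if (length(p)) mat[i, seq_along(p)] <- unclass(p)
  }
  mat
}

# Shallowest rank index at which two full lineages disagree (7 = identical).
divergence_rank_index <- function(a, b) {
  la <- unclass(a); lb <- unclass(b)
  n <- min(length(la), length(lb))
  for (i in seq_len(n)) if (la[i] != lb[i]) return(i)
  n + 1L
}
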