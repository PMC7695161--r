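# Alpha-diversity indices and the taxonomic rank summary table.

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) == 0L || any(counts < 0) || anyNA(counts))
    stop_format("counts must be non-negative and non-missing")
  if (sum(counts) <= 0) stop_format("counts must contain at least one positive entry")
  counts
}

#' Shannon diversity
#'
#' `H = -sum(p_i * log(p_i))` over positive categories, natural log
#' (computed through [vegan::diversity()]).
#'
#' @param counts Non-negative count (or abundance) vector with at least one
#'   positive entry.
#' @return Shannon H (natural log units).
#' @export
shannon_diversity <- function(counts) {
  counts <- check_counts(counts)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Simpson indices
#'
#' The plug-in Simpson family: dominance `D = sum(p_i^2)`, the complement
#' `I = 1 - D` and the reciprocal `R = 1 / D`. `I` and `R` are derived from
#' the one computed `D`, so the identities hold to machine precision.
#'
#' @inheritParams shannon_diversity
#' @return Named list with `D`, `I`, `R`.
#' @export
simpson_diversity <- function(counts) {
  counts <- check_counts(counts)
  D <- 1 - unname(vegan::diversity(counts, index = "simpson"))
  simpson_identities(D)
}

#' Simpson identities from a dominance value
#'
#' Derives the complement and reciprocal forms from a Simpson dominance
#' `D`, e.g. to check published index tables for internal consistency.
#'
#' @param D Simpson dominance in (0, 1].
#' @return Named list with `D`, `I = 1 - D`, `R = 1 / D`.
#' @export
simpson_identities <- function(D) {
  stopifnot(D > 0, D <= 1)
  list(D = D, I = 1 - D, R = 1 / D)
}

#' Pielou evenness
#'
#' `J = H / ln(S)` for richness `S >= 2`; by convention `J = 1` for a
#' single-category community (where `H` must be 0). An `H` exceeding the
#' maximum-entropy bound `ln(S)` beyond numerical tolerance is rejected as
#' inconsistent input.
#'
#' @param H Shannon diversity (natural log).
#' @param richness Number of categories, `S >= 1`.
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(H, richness) {
  stopifnot(richness >= 1L, H >= 0)
  if (richness == 1L) {
    if (H > 1e-8) stop_format("H > 0 is inconsistent with richness 1")
    return(1)
  }
  if (H > log(richness) + 1e-8)
    stop_format("H = %.4f exceeds ln(S) = %.4f: inconsistent input", H, log(richness))
  min(1, H / log(richness))
}

#' All diversity indices of a count vector
#'
#' @inheritParams shannon_diversity
#' @return List of class `diversity_result`: `shannon_H`, `simpson_D`,
#'   `simpson_I`, `simpson_R`, `evenness_J`, `richness_S`.
#' @export
diversity_indices <- function(counts) {
  counts <- check_counts(counts)
  H <- shannon_diversity(counts)
  simp <- simpson_diversity(counts)
  S <- sum(counts > 0)
  structure(list(shannon_H = H, simpson_D = simp$D, simpson_I = simp$I,
                 simpson_R = simp$R,
                 evenness_J = pielou_evenness(H, S), richness_S = S),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf(
    "S = %d  H = %.3f  J = %.3f  Simpson D = %.3f  I = %.3f  R = %.3f\n",
    x$richness_S, x$shannon_H, x$evenness_J, x$simpson_D, x$simpson_I,
    x$simpson_R))
  invisible(x)
}

#' Taxonomic rank summary table
#'
#' Summarises a set of LCA assignments the way rank-count tables are
#' reported: rows are phylum-level groups, the column for rank r counts the
#' distinct taxa whose assignment terminates exactly at rank r, the row
#' total sums across ranks, and a final `Total` row gives the per-rank grand
#' totals. Queries labelled `"unknown"` or `"unknown-eukaryotic"` are
#' excluded from the table and counted separately in the `"n_unknown"`
#' attribute.
#'
#' @param assignments Either a list of `lca_assignment` objects or a
#'   flattened table from [assignments_table()].
#' @return `data.frame` with columns `group`, the six ranks and `total`,
#'   plus attribute `n_unknown`.
#' @export
rank_summary <- function(assignments) {
  if (!is.data.frame(assignments)) assignments <- assignments_table(assignments)
  ranks <- tax_ranks()
  unknown <- assignments$assigned_rank %in% c("unknown", "unknown-eukaryotic")
  tab <- assignments[!unknown, , drop = FALSE]
  if (nrow(tab) > 0L && anyNA(tab$phylum))
    stop_format("assignment with malformed lineage: assigned but no phylum")
  empty <- as.data.frame(c(list(group = character()),
                           sapply(ranks, function(r) integer(0), simplify = FALSE),
                           list(total = integer())))
  if (nrow(tab) == 0L) {
    attr(empty, "n_unknown") <- sum(unknown)
    return(empty)
  }
  depth <- match(tab$assigned_rank, ranks)
  # one taxon = one distinct truncated lineage; count each once
  key <- vapply(seq_len(nrow(tab)), function(i) {
    paste(unlist(tab[i, ranks[seq_len(depth[i])]]), collapse = ";")
  }, character(1))
  first <- !duplicated(key)
  tab <- tab[first, , drop = FALSE]
  depth <- depth[first]
  groups <- sort(unique(tab$phylum))
  mat <- matrix(0L, nrow = length(groups), ncol = length(ranks),
                dimnames = list(groups, ranks))
  for (i in seq_len(nrow(tab))) {
    mat[tab$phylum[i], depth[i]] <- mat[tab$phylum[i], depth[i]] + 1L
  }
  out <- data.frame(group = groups, mat, row.names = NULL)
  out$total <- as.integer(rowSums(mat))
  totals <- data.frame(group = "Total",
                       t(vapply(colSums(mat), as.integer, integer(1))),
                       total = as.integer(sum(mat)), row.names = NULL)
  out <- rbind(out, totals)
  attr(out, "n_unknown") <- sum(unknown)
  out
}

#' Read a rank-count table
#'
#' Reads a TSV with a `group` column and one count column per rank of
#' [tax_ranks()] (e.g. the packaged published rank-count fixture under
#' `inst/extdata`).
#'
#' @param path TSV path.
#' @return `data.frame` with `group` and the six rank columns.
#' @export
read_rank_counts <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  needed <- c("group", tax_ranks())
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop_format("rank-count table missing column(s): %s", paste(missing, collapse = ", "))
  tab[, needed, drop = FALSE]
}

#' Re-sum a rank-count table
#'
#' Computes row totals and per-rank grand totals of a rank-count table ---
#' the internal-consistency check for published tables of this form.
#'
#' @param tab Table from [read_rank_counts()] or [rank_summary()] (without
#'   its `Total` row).
#' @return List with `row_totals` (named by group) and `grand_totals`
#'   (named by rank, plus `total`).
#' @export
rank_table_totals <- function(tab) {
  tab <- tab[tab$group != "Total", , drop = FALSE]
  ranks <- tax_ranks()
  m <- as.matrix(tab[, ranks])
  storage.mode(m) <- "integer"
  list(row_totals = setNames(as.integer(rowSums(m)), tab$group),
       grand_totals = c(setNames(as.integer(colSums(m)), ranks),
                        total = sum(m)))
}
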