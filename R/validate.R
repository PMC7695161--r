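# Validation procedures for the reassembled barcodes: half-split accession
# concordance and synthetic chimera injection.

#' Split a sequence into two approximately equal halves
#'
#' Sequences of at least 400 bp split at the midpoint with no overlap
#' (`[1, ceil(L/2)]` and `[floor(L/2) + 1, L]`). Shorter sequences get a
#' small overlap so each half retains enough signal for an independent
#' search: each half is extended `overlap_half` bp past the midpoint
#' (clipped to the sequence ends), giving a `2 * overlap_half` bp overlap.
#'
#' @param seq DNA string of length >= 100.
#' @param overlap_half Per-half extension (bp) applied below 400 bp.
#' @return Character vector of the two halves.
#' @export
split_halves <- function(seq, overlap_half = 25L) {
  L <- nchar(seq)
  if (L < 100L) stop_format("split_halves: sequence shorter than 100 bp")
  if (L >= 400L) {
    h1 <- substring(seq, 1L, ceiling(L / 2))
    h2 <- substring(seq, floor(L / 2) + 1L, L)
  } else {
    h1 <- substring(seq, 1L, min(L, ceiling(L / 2) + overlap_half))
    h2 <- substring(seq, max(1L, floor(L / 2) + 1L - overlap_half), L)
  }
  c(h1, h2)
}

#' Half-split concordance test
#'
#' For each query the two halves are searched independently (sensitive
#' mode); the query is concordant when the best-hit subject of the first
#' half occurs among the top four subjects of the second half (and, in the
#' relaxed variant, among the top eight). Queries where either half returns
#' no hit are counted in the denominator but cannot be concordant; since
#' either denominator convention is defensible, hit-only fractions are
#' reported alongside.
#'
#' @param seqs Character vector of query sequences.
#' @param refdb A [ref_db()].
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @return List of class `concordance_report`: `n_queries`,
#'   `concordant_top4`, `concordant_top8`, `fraction_top4`, `fraction_top8`,
#'   `n_with_hits`, `fraction_top4_with_hits`, `fraction_top8_with_hits`.
#' @export
half_concordance <- function(seqs, refdb, config = pipeline_config(),
                             scheme = scoring_scheme()) {
  stopifnot(inherits(refdb, "ref_db"), length(refdb) > 0L)
  n <- length(seqs)
  c4 <- 0L; c8 <- 0L; with_hits <- 0L
  for (s in seqs) {
    halves <- split_halves(s)
    h1 <- search_refdb(halves[1L], refdb, mode = "sensitive", config = config,
                       scheme = scheme, top_hits = 4L)
    h2 <- search_refdb(halves[2L], refdb, mode = "sensitive", config = config,
                       scheme = scheme, top_hits = 8L)
    if (nrow(h1) == 0L || nrow(h2) == 0L) next
    with_hits <- with_hits + 1L
    best1 <- h1$subject_id[1L]
    if (best1 %in% head(h2$subject_id, 4L)) c4 <- c4 + 1L
    if (best1 %in% head(h2$subject_id, 8L)) c8 <- c8 + 1L
  }
  frac <- function(x, d) if (d > 0L) x / d else NA_real_
  structure(list(n_queries = n, concordant_top4 = c4, concordant_top8 = c8,
                 fraction_top4 = frac(c4, n), fraction_top8 = frac(c8, n),
                 n_with_hits = with_hits,
                 fraction_top4_with_hits = frac(c4, with_hits),
                 fraction_top8_with_hits = frac(c8, with_hits)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("half-split concordance: %d queries, top4 %s, top8 %s\n",
              x$n_queries,
              ifelse(is.na(x$fraction_top4), "NA", sprintf("%.3f", x$fraction_top4)),
              ifelse(is.na(x$fraction_top8), "NA", sprintf("%.3f", x$fraction_top8))))
  invisible(x)
}

#' Construct synthetic chimeric sequences
#'
#' Builds artificial barcodes by concatenating 2--3 fragments (150--400 bp
#' each, total at most `max_len`) drawn from reference sequences whose
#' lineages differ at class rank or above. Mirroring the construction from
#' arthropod and vertebrate donors, adjacent fragments are drawn from
#' different phyla whenever the database contains more than one phylum, and
#' from different classes otherwise. The donor log is attached as the
#' `"donors"` attribute.
#'
#' @param refdb A [ref_db()] containing at least two classes.
#' @param n Number of chimeras.
#' @param seed Integer RNG seed.
#' @param max_len Maximum chimera length (bp).
#' @return Character vector of `n` chimeric sequences, with a donor-log
#'   `data.frame` (`chimera`, `fragment`, `donor_id`) as attribute `donors`.
#' @export
make_chimeras <- function(refdb, n = 100L, seed = 1L, max_len = 712L) {
  stopifnot(inherits(refdb, "ref_db"))
  lm <- lineage_matrix(refdb$taxonomy)
  if (length(unique(lm[, "class"])) < 2L)
    stop_format("make_chimeras: reference set must contain >= 2 classes")
  cross_rank <- if (length(unique(lm[, "phylum"])) >= 2L) "phylum" else "class"
  if (n == 0L) {
    out <- character(0)
    attr(out, "donors") <- data.frame(chimera = integer(), fragment = integer(),
                                      donor_id = character())
    return(out)
  }
  ids <- rownames(lm)
  n_groups <- length(unique(lm[, cross_rank]))
  withr::with_seed(seed, {
    out <- character(n)
    log <- list()
    for (i in seq_len(n)) {
      # all donors of one chimera come from pairwise-different groups, so
      # any two of its fragments support conflicting lineages
      k <- if (n_groups >= 3L) sample(2:3, 1L) else 2L
      max_frag <- min(400L, floor(max_len / k))
      donors <- character(k)
      groups <- sample(unique(lm[, cross_rank]), k)
      for (j in seq_len(k)) {
        pool <- ids[lm[, cross_rank] == groups[j]]
        donors[j] <- pool[sample.int(length(pool), 1L)]
      }
      parts <- vapply(donors, function(d) {
        s <- refdb$seqs[[d]]
        flen <- sample(150:max_frag, 1L)
        start <- sample.int(nchar(s) - flen + 1L, 1L)
        substring(s, start, start + flen - 1L)
      }, character(1))
      out[i] <- paste(parts, collapse = "")
      log[[i]] <- data.frame(chimera = i, fragment = seq_len(k), donor_id = donors)
    }
    attr(out, "donors") <- do.call(rbind, log)
    out
  })
}

#' Chimera injection test
#'
#' Runs each chimera through the same half-split + search + LCA path used
#' for real queries: both halves are searched (sensitive mode), the
#' retained hits are pooled and [lca_assign()] is applied. The summary
#' counts queries labelled `"unknown"` or `"unknown-eukaryotic"` --- for
#' genuine cross-class chimeras the two halves support conflicting
#' lineages, so the strict LCA cannot resolve them.
#'
#' @param chimeras Character vector from [make_chimeras()] (any query set
#'   can be passed; non-chimeric sequences should come back assigned).
#' @param refdb A [ref_db()].
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @return List with `assignments` (list of `lca_assignment`), `table`
#'   (the flattened assignment table) and `n_unknown`.
#' @export
chimera_rank_test <- function(chimeras, refdb, config = pipeline_config(),
                              scheme = scoring_scheme()) {
  stopifnot(inherits(refdb, "ref_db"), length(refdb) > 0L)
  asg <- vector("list", length(chimeras))
  for (i in seq_along(chimeras)) {
    qid <- sprintf("chimera%03d", i)
    halves <- split_halves(chimeras[[i]])
    hits <- rbind(
      search_refdb(halves[1L], refdb, mode = "sensitive", config = config,
                   scheme = scheme, query_id = qid),
      search_refdb(halves[2L], refdb, mode = "sensitive", config = config,
                   scheme = scheme, query_id = qid))
    asg[[i]] <- lca_assign(hits, refdb$taxonomy, query_id = qid)
  }
  tab <- assignments_table(asg)
  n_unknown <- sum(tab$assigned_rank %in% c("unknown", "unknown-eukaryotic"))
  list(assignments = asg, table = tab, n_unknown = n_unknown)
}
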