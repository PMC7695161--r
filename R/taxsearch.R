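# Seeded local-alignment search against the taxonomy-annotated reference set,
# with Karlin-Altschul e-values, two sensitivity modes (long exact seeds for
# "highly similar" searches, short seeds for "somewhat similar" ones) and
# strict LCA consensus rank assignment.

#' Alignment scoring scheme
#'
#' Scoring and statistical constants for the local-alignment search. The
#' defaults (+1 match, -2 mismatch, gap open 2 / extend 1, lambda = 1.28,
#' K = 0.46) are the standard constants used for ungapped-style nucleotide
#' scoring; they are configurable because e-values, and hence hit retention,
#' depend on them.
#'
#' @param match Positive integer match reward.
#' @param mismatch Negative integer mismatch penalty.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param lambda,K Karlin-Altschul statistical parameters (> 0).
#' @param seed_len Exact-match seed length; `NULL` selects 28 for
#'   `"high-identity"` mode and 11 for `"sensitive"` mode at search time.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = 2L,
                           gap_extend = 1L, lambda = 1.28, K = 0.46,
                           seed_len = NULL) {
  if (!(match > 0L) || !(mismatch < 0L))
    stop_format("scoring scheme requires match > 0 > mismatch")
  if (lambda <= 0 || K <= 0) stop_format("lambda and K must be positive")
  if (!is.null(seed_len) && seed_len < 8L)
    stop_format("seed_len must be >= 8")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 seed_len = if (is.null(seed_len)) NULL else as.integer(seed_len)),
            class = "scoring_scheme")
}

#' Karlin-Altschul e-value
#'
#' Expected number of local alignments scoring at least `raw_score` between
#' a random query of length `query_len` and a database of total length
#' `db_len`: `E = K * m * n * exp(-lambda * S)`. Strictly decreasing in the
#' score and linear in either length.
#'
#' @param raw_score Integer alignment raw score.
#' @param query_len,db_len Positive lengths in bp.
#' @param scheme A [scoring_scheme()].
#' @return The e-value (positive real).
#' @export
alignment_evalue <- function(raw_score, query_len, db_len,
                             scheme = scoring_scheme()) {
  if (query_len <= 0 || db_len <= 0)
    stop_format("query and database lengths must be positive")
  scheme$K * query_len * db_len * exp(-scheme$lambda * raw_score)
}

# Local alignment of a query orientation against many subjects in one
# vectorised call (local alignment is symmetric in its arguments, so the
# subjects are passed as the pattern set). Returns one row per subject with
# score, identity (matching columns / alignment columns) and alignment
# length.
local_align_many <- function(query, subjects, scheme) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                                     mismatch = scheme$mismatch,
                                                     baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(subjects),
                                       Biostrings::DNAString(query),
                                       type = "local",
                                       substitutionMatrix = submat,
                                       gapOpening = scheme$gap_open,
                                       gapExtension = scheme$gap_extend)
  # identity = matching columns / alignment columns (internal gaps included);
  # a local alignment has no end gaps, so PID1 is exactly this ratio
  ncols <- Biostrings::nchar(aln)
  data.frame(score = Biostrings::score(aln),
             identity = Biostrings::pid(aln, type = "PID1") / 100,
             align_len = ncols)
}

# Single-pair convenience wrapper.
local_align <- function(query, subject, scheme) {
  as.list(local_align_many(query, subject, scheme)[1L, ])
}

# Index the query's seed k-mers per orientation: kmer -> bitmask
# (1 = forward query, 2 = reverse-complement query).
query_seed_index <- function(orientations, seed_len) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (oi in seq_along(orientations)) {
    bit <- if (oi == 1L) 1L else 2L
    for (km in unique(seq_kmers(orientations[[oi]], seed_len))) {
      cur <- get0(km, envir = env, inherits = FALSE)
      assign(km, bitwOr(cur %||% 0L, bit), envir = env)
    }
  }
  env
}

# Which query orientations share an exact seed with this subject (bitmask).
subject_seed_mask <- function(subject, seed_len, qenv) {
  mask <- 0L
  for (km in seq_kmers(subject, seed_len)) {
    v <- get0(km, envir = qenv, inherits = FALSE)
    if (!is.null(v)) {
      mask <- bitwOr(mask, v)
      if (mask == 3L) break
    }
  }
  mask
}

#' Search a query against the reference database
#'
#' Exact-match seeds of length 28 (`"high-identity"` mode, emulating a
#' highly-similar search) or 11 (`"sensitive"` mode, emulating a
#' somewhat-similar search) are sought on both strands; seeded subjects are
#' aligned locally with the configured scoring scheme. Hits are filtered to
#' identity >= `config$min_hit_identity` and e-value <= `config$max_evalue`,
#' sorted by raw score (ties broken by subject id, so results do not depend
#' on database input order) and truncated to the `top_hits` best.
#'
#' @param query DNA string.
#' @param refdb A [ref_db()].
#' @param mode `"high-identity"` or `"sensitive"`.
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param top_hits Override for the number of hits retained.
#' @param query_id Identifier recorded in the hit table.
#' @return `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity` (fraction), `align_len`, `raw_score`, `evalue`.
#' @export
search_refdb <- function(query, refdb, mode = c("sensitive", "high-identity"),
                         config = pipeline_config(),
                         scheme = scoring_scheme(),
                         top_hits = config$top_hits,
                         query_id = "query") {
  mode <- match.arg(mode)
  stopifnot(inherits(refdb, "ref_db"))
  if (length(refdb) == 0L) stop_format("search: empty reference database")
  if (is.na(query) || !nzchar(query)) stop_format("search: empty query")
  seed_len <- scheme$seed_len %||% if (mode == "high-identity") 28L else 11L
  db_len <- sum(nchar(refdb$seqs))
  qlen <- nchar(query)
  orientations <- c(query, revcomp(query))
  qenv <- query_seed_index(orientations, seed_len)
  sids <- names(refdb$seqs)
  masks <- vapply(sids, function(sid)
    subject_seed_mask(refdb$seqs[[sid]], seed_len, qenv), integer(1))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      percent_identity = numeric(), align_len = integer(),
                      raw_score = numeric(), evalue = numeric())
  if (all(masks == 0L)) return(empty)

  best <- NULL  # per-subject best over orientations
  for (oi in 1:2) {
    sel <- sids[bitwAnd(masks, oi) > 0L]
    if (length(sel) == 0L) next
    a <- local_align_many(orientations[[oi]], unname(refdb$seqs[sel]), scheme)
    a$subject_id <- sel
    if (is.null(best)) best <- a
    else {
      prev <- match(sel, best$subject_id)
      new_rows <- is.na(prev)
      upgrade <- !new_rows & a$score > best$score[prev]
      if (any(upgrade))
        best[prev[upgrade], c("score", "identity", "align_len")] <-
          a[upgrade, c("score", "identity", "align_len")]
      if (any(new_rows)) best <- rbind(best, a[new_rows, , drop = FALSE])
    }
  }
  best$evalue <- alignment_evalue(best$score, qlen, db_len, scheme)
  keep <- best$identity + 1e-12 >= config$min_hit_identity &
    best$evalue <= config$max_evalue
  best <- best[keep, , drop = FALSE]
  if (nrow(best) == 0L) return(empty)
  tab <- data.frame(query_id = query_id, subject_id = best$subject_id,
                    percent_identity = best$identity,
                    align_len = best$align_len, raw_score = best$score,
                    evalue = best$evalue)
  tab <- tab[order(-tab$raw_score, tab$subject_id), , drop = FALSE]
  rownames(tab) <- NULL
  head(tab, top_hits)
}

#' Strict LCA consensus assignment
#'
#' Assigns a query the deepest taxonomic rank on which all retained hits
#' agree: the lineage is the longest common rank prefix of the hit
#' lineages. No hits gives the label `"unknown"`; hits whose lineages share
#' no rank at all (conflict already at phylum) give `"unknown-eukaryotic"`.
#' All retained hits weigh equally (strict consensus, no majority rule).
#'
#' @param hits Hit table from [search_refdb()] (possibly from several
#'   searches pooled over one query).
#' @param taxonomy Named list of [taxon_path()] lineages covering every hit
#'   subject.
#' @param query_id Identifier recorded on the assignment.
#' @return List of class `lca_assignment`: `query_id`, `lineage`
#'   (a [taxon_path()], possibly empty), `assigned_rank` (rank label,
#'   `"unknown"` or `"unknown-eukaryotic"`), `supporting_hits`.
#' @export
lca_assign <- function(hits, taxonomy, query_id = NULL) {
  query_id <- query_id %||%
    (if (nrow(hits) > 0L) hits$query_id[1L] else "query")
  if (nrow(hits) == 0L) {
    return(structure(list(query_id = query_id, lineage = taxon_path(),
                          assigned_rank = "unknown", supporting_hits = 0L),
                     class = "lca_assignment"))
  }
  missing <- setdiff(unique(hits$subject_id), names(taxonomy))
  if (length(missing))
    stop_format("lca_assign: no lineage for subject(s): %s",
                paste(head(missing, 5L), collapse = ", "))
  lins <- lapply(unique(hits$subject_id), function(sid) unclass(taxonomy[[sid]]))
  depth <- min(lengths(lins))
  common <- character(0)
  for (r in seq_len(depth)) {
    vals <- vapply(lins, `[[`, character(1), r)
    if (length(unique(vals)) == 1L) common <- c(common, vals[1L]) else break
  }
  if (length(common) == 0L) {
    return(structure(list(query_id = query_id, lineage = taxon_path(),
                          assigned_rank = "unknown-eukaryotic",
                          supporting_hits = nrow(hits)),
                     class = "lca_assignment"))
  }
  structure(list(query_id = query_id, lineage = taxon_path(common),
                 assigned_rank = tax_ranks()[length(common)],
                 supporting_hits = nrow(hits)),
            class = "lca_assignment")
}

#' @export
print.lca_assignment <- function(x, ...) {
  lin <- if (length(x$lineage)) paste(unclass(x$lineage), collapse = "; ") else "-"
  cat(sprintf("%s: %s [%s] (%d hits)\n", x$query_id, x$assigned_rank, lin,
              x$supporting_hits))
  invisible(x)
}

#' Flatten assignments into a table
#'
#' @param assignments List of `lca_assignment` objects.
#' @return `data.frame` with `query_id`, `assigned_rank`, `supporting_hits`
#'   and one column per rank of [tax_ranks()] (`NA` where truncated).
#' @export
assignments_table <- function(assignments) {
  ranks <- tax_ranks()
  rows <- lapply(assignments, function(a) {
    lin <- rep(NA_character_, 6L)
    if (length(a$lineage)) lin[seq_along(a$lineage)] <- unclass(a$lineage)
    cbind(data.frame(query_id = a$query_id, assigned_rank = a$assigned_rank,
                     supporting_hits = a$supporting_hits),
          as.data.frame(as.list(setNames(lin, ranks)), stringsAsFactors = FALSE))
  })
  if (length(rows) == 0L) {
    return(cbind(data.frame(query_id = character(), assigned_rank = character(),
                            supporting_hits = integer()),
                 as.data.frame(sapply(ranks, function(r) character(0),
                                      simplify = FALSE))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a set of queries end to end
#'
#' Convenience wrapper: searches every query in the given mode and applies
#' [lca_assign()] to each hit list.
#'
#' @param queries Named character vector of query sequences.
#' @param refdb A [ref_db()].
#' @param mode Search mode (see [search_refdb()]).
#' @param config,scheme Pipeline configuration and scoring scheme.
#' @return List with `assignments` (list of `lca_assignment`) and `hits`
#'   (pooled hit table).
#' @export
assign_queries <- function(queries, refdb, mode = "sensitive",
                           config = pipeline_config(),
                           scheme = scoring_scheme()) {
  if (is.null(names(queries)))
    names(queries) <- sprintf("q%04d", seq_along(queries))
  hit_tabs <- list(); asg <- list()
  for (qid in names(queries)) {
    hits <- search_refdb(queries[[qid]], refdb, mode = mode, config = config,
                         scheme = scheme, query_id = qid)
    hit_tabs[[qid]] <- hits
    asg[[qid]] <- lca_assign(hits, refdb$taxonomy, query_id = qid)
  }
  list(assignments = asg, hits = do.call(rbind, c(hit_tabs, list(make.row.names = FALSE))))
}

#' Compare species recovered by two search modes
#'
#' Reports the asymmetry between two assignment sets at species rank: the
#' fraction of species found by one mode but absent from the other, and the
#' intersection.
#'
#' @param a,b Lists of `lca_assignment` objects over the same query set.
#' @return List with `species_a`, `species_b`, `n_intersection`,
#'   `frac_a_not_b`, `frac_b_not_a` (fractions are `NA` when the
#'   corresponding species set is empty).
#' @export
compare_modes <- function(a, b) {
  species_of <- function(x) {
    sp <- vapply(x, function(z) {
      if (identical(z$assigned_rank, "species")) unclass(z$lineage)[["species"]]
      else NA_character_
    }, character(1))
    unique(sp[!is.na(sp)])
  }
  sa <- species_of(a); sb <- species_of(b)
  list(species_a = sa, species_b = sb,
       n_intersection = length(intersect(sa, sb)),
       frac_a_not_b = if (length(sa)) length(setdiff(sa, sb)) / length(sa) else NA_real_,
       frac_b_not_a = if (length(sb)) length(setdiff(sb, sa)) / length(sb) else NA_real_)
}
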