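# Length filtering, dereplication, chimera screening, greedy 98% centroid
# clustering and consensus extraction over assembled contigs.

#' Filter contigs by maximum plausible barcode length
#'
#' Assembled sequences longer than the theoretical primer-to-primer product
#' (~710 bp; 712 bp is used as the cutoff to absorb primer-site and assembly
#' length variation) are treated as assembly artefacts or non-target
#' sequences and removed.
#'
#' @param contigs Contig table (columns `id`, `seq`, `length`).
#' @param max_len Maximum retained length in bp; contigs with
#'   `length > max_len` are removed.
#' @return List with elements `kept` and `removed`, an exact partition of
#'   the input rows.
#' @export
length_filter <- function(contigs, max_len = 712L) {
  stopifnot(max_len > 0L)
  if (is.null(contigs) || nrow(contigs) == 0L) {
    return(list(kept = contigs, removed = contigs))
  }
  keep <- contigs$length <= max_len
  list(kept = contigs[keep, , drop = FALSE],
       removed = contigs[!keep, , drop = FALSE])
}

#' Dereplicate sequences into unique features
#'
#' Collapses exact full-length replicates (after canonical orientation,
#' since assembly strand is arbitrary) into unique sequence features with
#' replicate counts, sorted by decreasing size with lexicographic
#' tie-breaking.
#'
#' @param seqs Character vector of DNA sequences.
#' @return `data.frame` with columns `seq` and `size`.
#' @export
dereplicate <- function(seqs) {
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(), size = integer()))
  }
  canon <- canonical_orientation(toupper(seqs))
  tab <- table(canon)
  feats <- data.frame(seq = names(tab), size = as.integer(tab), row.names = NULL)
  feats <- feats[order(-feats$size, feats$seq), , drop = FALSE]
  rownames(feats) <- NULL
  feats
}

#' Reference-based chimera screen
#'
#' A feature is flagged as chimeric when its two halves (the same split used
#' by the half-split validation, [split_halves()]) have best database
#' matches whose lineages disagree at class rank or above, while each half
#' matches its best subject at 85% identity or better. Features with no hit
#' on either half are kept: absence of evidence is not treated as chimerism.
#'
#' @param features Feature table from [dereplicate()].
#' @param refdb A [ref_db()].
#' @param config A [pipeline_config()].
#' @param scheme A [scoring_scheme()].
#' @param min_half_identity Identity floor for a half-hit to count as
#'   evidence.
#' @return List with elements `clean` and `flagged` (feature tables).
#' @export
flag_chimeras <- function(features, refdb, config = pipeline_config(),
                          scheme = scoring_scheme(),
                          min_half_identity = 0.85) {
  stopifnot(inherits(refdb, "ref_db"), length(refdb) > 0L)
  if (nrow(features) == 0L) return(list(clean = features, flagged = features))
  is_chim <- logical(nrow(features))
  for (i in seq_len(nrow(features))) {
    s <- features$seq[i]
    if (nchar(s) < 100L) next
    halves <- split_halves(s)
    best <- lapply(halves, function(h) {
      hits <- search_refdb(h, refdb, mode = "sensitive", config = config,
                           scheme = scheme)
      if (nrow(hits) == 0L) NULL else hits[1L, ]
    })
    if (is.null(best[[1]]) || is.null(best[[2]])) next
    if (best[[1]]$percent_identity < min_half_identity ||
        best[[2]]$percent_identity < min_half_identity) next
    lin1 <- refdb$taxonomy[[best[[1]]$subject_id]]
    lin2 <- refdb$taxonomy[[best[[2]]$subject_id]]
    # disagreement at class rank or above = split no deeper than rank 2
    if (divergence_rank_index(lin1, lin2) <= 2L) is_chim[i] <- TRUE
  }
  list(clean = features[!is_chim, , drop = FALSE],
       flagged = features[is_chim, , drop = FALSE])
}

# Global alignment identity: matching columns / alignment columns (gaps and
# end gaps included in the denominator). This convention is strict, so
# cluster membership does not depend on how end gaps are discounted.
global_identity <- function(a, b) {
  if (a == b) return(1)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 2, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1]]
  sum(pa == sa & pa != "-") / length(pa)
}

#' Greedy centroid clustering
#'
#' The classical greedy OTU construction: features are scanned in decreasing
#' size order (re-sorted internally); each feature joins the first existing
#' centroid it matches at global-alignment identity `identity` or better,
#' otherwise it founds a new cluster. Identity is matching columns divided
#' by alignment columns, gaps included. Both strands of a feature are
#' compared (canonical orientation can flip between near-identical
#' sequences, so strand is resolved at comparison time); members are stored
#' in centroid orientation.
#'
#' @param features Feature table from [dereplicate()].
#' @param identity Clustering identity threshold in (0, 1].
#' @return List of clusters; each cluster is a list with `centroid`,
#'   `members` (feature table), `total_size` and `consensus`.
#' @export
cluster_greedy <- function(features, identity = 0.98) {
  stopifnot(identity > 0, identity <= 1)
  features <- features[order(-features$size, features$seq), , drop = FALSE]
  clusters <- list()
  centroids <- character()
  for (i in seq_len(nrow(features))) {
    s <- features$seq[i]
    joined <- FALSE
    for (ci in seq_along(centroids)) {
      # a length gap alone can rule the pair out without aligning
      lmax <- max(nchar(s), nchar(centroids[ci]))
      if ((lmax - min(nchar(s), nchar(centroids[ci]))) / lmax > 1 - identity + 1e-12) next
      oriented <- s
      ident <- global_identity(s, centroids[ci])
      if (ident < identity - 1e-12) {
        rc_ident <- global_identity(revcomp(s), centroids[ci])
        if (rc_ident > ident) { ident <- rc_ident; oriented <- revcomp(s) }
      }
      if (ident >= identity - 1e-12) {
        row <- features[i, ]
        row$seq <- oriented
        clusters[[ci]]$members <- rbind(clusters[[ci]]$members, row)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, s)
      clusters[[length(clusters) + 1L]] <- list(centroid = s,
                                                members = features[i, ])
    }
  }
  lapply(clusters, function(cl) {
    rownames(cl$members) <- NULL
    cl$total_size <- sum(cl$members$size)
    cl$consensus <- cluster_consensus(cl)
    class(cl) <- "otu_cluster"
    cl
  })
}

#' Consensus sequence of a cluster
#'
#' Column-wise majority over the member-to-centroid pairwise alignments,
#' weighting each member by its replicate size. Ties are broken toward the
#' centroid base; member insertions relative to the centroid are ignored; a
#' centroid column is dropped only when deletion votes strictly win.
#'
#' @param cluster A cluster as produced by [cluster_greedy()] (list with
#'   `centroid` and `members`).
#' @return The consensus DNA string.
#' @export
cluster_consensus <- function(cluster) {
  cen <- cluster$centroid
  members <- cluster$members
  stopifnot(nrow(members) >= 1L)
  if (nrow(members) == 1L) return(members$seq[1L])
  L <- nchar(cen)
  alpha <- c(DNA_BASES, "-")
  votes <- matrix(0, nrow = 5L, ncol = L, dimnames = list(alpha, NULL))
  cen_chars <- strsplit(cen, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(members))) {
    m <- members$seq[i]; w <- members$size[i]
    if (m == cen) {
      votes[cbind(match(cen_chars, alpha), seq_len(L))] <-
        votes[cbind(match(cen_chars, alpha), seq_len(L))] + w
      next
    }
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                       baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(m),
                                         Biostrings::DNAString(cen),
                                         type = "global",
                                         substitutionMatrix = submat,
                                         gapOpening = 2, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "", fixed = TRUE)[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "", fixed = TRUE)[[1]]
    cen_pos <- cumsum(sa != "-")
    keep <- sa != "-"
    votes[cbind(match(pa[keep], alpha), cen_pos[keep])] <-
      votes[cbind(match(pa[keep], alpha), cen_pos[keep])] + w
  }
  out <- character(L)
  for (j in seq_len(L)) {
    v <- votes[, j]
    best <- max(v)
    winners <- alpha[v == best]
    pick <- if (cen_chars[j] %in% winners) cen_chars[j] else winners[1L]
    out[j] <- pick
  }
  paste(out[out != "-"], collapse = "")
}

#' Write cluster membership table
#'
#' @param clusters List from [cluster_greedy()].
#' @param path Output TSV path (optional).
#' @return `data.frame` with columns `cluster`, `feature_seq`, `size`,
#'   `is_centroid`.
#' @export
cluster_table <- function(clusters, path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(clusters), function(ci) {
    cl <- clusters[[ci]]
    data.frame(cluster = sprintf("OTU%04d", ci),
               feature_seq = cl$members$seq,
               size = cl$members$size,
               is_centroid = cl$members$seq == cl$centroid)
  }))
  if (is.null(rows)) {
    rows <- data.frame(cluster = character(), feature_seq = character(),
                       size = integer(), is_centroid = logical())
  }
  if (!is.null(path)) {
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rows
}
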