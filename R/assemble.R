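# De Bruijn assembly of the ~710 bp barcode from short sheared fragments.
#
# The amplicon pool is treated as a collection of miniature genomes: reads
# (and their reverse complements) are decomposed into k-mers, the k-mer
# graph is cleaned (singleton k-mers at high depth, short tips, small
# bubbles) and maximal unbranched paths are emitted as contigs. The graph is
# strand-symmetric by construction; contigs are reported in canonical
# orientation so output is independent of read strand and input order.

# ---- k-mer graph primitives -------------------------------------------------

# Count k-mers of a character vector of reads, both strands.
count_kmers <- function(seqs, k) {
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) return(integer(0))
  both <- c(seqs, revcomp(seqs))
  km <- unlist(lapply(both, seq_kmers, k = k), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  tab <- table(km)
  setNames(as.integer(tab), names(tab))
}

# Environment-backed k-mer set with counts, for O(1) membership tests.
kmer_env <- function(counts) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(counts) * 2L)
  nm <- names(counts)
  for (i in seq_along(counts)) assign(nm[i], counts[i], envir = env)
  env
}

kmer_count <- function(env, km) {
  v <- get0(km, envir = env, inherits = FALSE)
  if (is.null(v)) 0L else v
}

successors <- function(env, km, k) {
  cand <- paste0(substring(km, 2L, k), DNA_BASES)
  cand[vapply(cand, function(x) !is.null(get0(x, envir = env, inherits = FALSE)), logical(1))]
}

predecessors <- function(env, km, k) {
  cand <- paste0(DNA_BASES, substring(km, 1L, k - 1L))
  cand[vapply(cand, function(x) !is.null(get0(x, envir = env, inherits = FALSE)), logical(1))]
}

# Maximal unbranched paths over the current k-mer set. Returns a data.frame
# of unitigs with sequence, mean k-mer coverage and end-degree information.
build_unitigs <- function(env, kmers, k) {
  if (length(kmers) == 0L) {
    return(data.frame(seq = character(), coverage = numeric(),
                      in_first = integer(), out_last = integer()))
  }
  visited <- new.env(hash = TRUE, parent = emptyenv(), size = length(kmers) * 2L)
  is_start <- function(km) {
    pre <- predecessors(env, km, k)
    length(pre) != 1L || length(successors(env, pre[1L], k)) > 1L
  }
  walk <- function(km) {
    path <- character(512L); n <- 0L
    cur <- km
    repeat {
      n <- n + 1L
      if (n > length(path)) path <- c(path, character(length(path)))
      path[n] <- cur
      assign(cur, TRUE, envir = visited)
      nxt <- successors(env, cur, k)
      if (length(nxt) != 1L) break
      if (length(predecessors(env, nxt[1L], k)) != 1L) break
      if (!is.null(get0(nxt[1L], envir = visited, inherits = FALSE))) break
      cur <- nxt[1L]
    }
    path[seq_len(n)]
  }
  res_seq <- character(); res_cov <- numeric()
  res_in <- integer(); res_out <- integer()
  emit <- function(path) {
    seq <- paste0(path[1L], paste(substring(path[-1L], k, k), collapse = ""))
    res_seq[[length(res_seq) + 1L]] <<- seq
    res_cov[[length(res_cov) + 1L]] <<-
      mean(vapply(path, kmer_count, integer(1), env = env))
    res_in[[length(res_in) + 1L]] <<-
      length(predecessors(env, path[1L], k))
    res_out[[length(res_out) + 1L]] <<-
      length(successors(env, path[length(path)], k))
  }
  starts <- kmers[vapply(kmers, is_start, logical(1))]
  for (km in starts) {
    if (is.null(get0(km, envir = visited, inherits = FALSE))) emit(walk(km))
  }
  # sweep anything unreached (isolated cycles)
  for (km in kmers) {
    if (is.null(get0(km, envir = visited, inherits = FALSE))) emit(walk(km))
  }
  data.frame(seq = res_seq, coverage = res_cov,
             in_first = res_in, out_last = res_out)
}

# Remove the k-mers of a set of unitig sequences (both strands) from counts.
drop_unitig_kmers <- function(counts, seqs, k) {
  if (length(seqs) == 0L) return(counts)
  both <- c(seqs, revcomp(seqs))
  km <- unique(unlist(lapply(both, seq_kmers, k = k), use.names = FALSE))
  counts[setdiff(names(counts), km)]
}

# ---- assembler --------------------------------------------------------------

#' Assemble read pairs into contigs
#'
#' Small de Bruijn graph assembler for barcode-scale targets. The graph is
#' built over both mates and their reverse complements. Cleaning follows
#' standard practice at this scale: k-mers seen once are dropped when the
#' median k-mer depth (over k-mer occurrences) is at least 10; dead-end
#' branches ("tips") shorter than `2k` are pruned; parallel paths sharing
#' both flanking junctions and differing by at most 2 substitutions
#' ("bubbles") are collapsed onto the higher-coverage branch. Maximal
#' unbranched paths of at least `min_contig_len` bp are reported in
#' canonical orientation with their mean k-mer coverage.
#'
#' @param pairs Read-pair table (columns `seq1`, `seq2`).
#' @param k Odd k-mer size smaller than the read length.
#' @param min_contig_len Minimum contig length in bp.
#' @return `data.frame` with columns `id`, `seq`, `length`, `mean_coverage`,
#'   sorted by decreasing length.
#' @export
assemble_reads <- function(pairs, k = 31L, min_contig_len = 200L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop_format("k must be odd")
  empty <- data.frame(id = character(), seq = character(),
                      length = integer(), mean_coverage = numeric())
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty)
  reads <- c(pairs$seq1, pairs$seq2)
  if (k >= max(nchar(reads))) stop_format("k must be smaller than the read length")

  counts <- count_kmers(reads, k)
  if (length(counts) == 0L) return(empty)
  # error k-mer cut: weighted median depth over k-mer occurrences
  med_depth <- median(rep.int(counts, counts))
  if (med_depth >= 10) counts <- counts[counts > 1L]
  if (length(counts) == 0L) return(empty)

  counts <- clean_graph(counts, k)

  env <- kmer_env(counts)
  uni <- build_unitigs(env, names(counts), k)
  uni$seq <- canonical_orientation(uni$seq)
  uni <- uni[!duplicated(uni$seq), , drop = FALSE]
  uni <- uni[nchar(uni$seq) >= min_contig_len, , drop = FALSE]
  ord <- order(-nchar(uni$seq), uni$seq)
  uni <- uni[ord, , drop = FALSE]
  if (nrow(uni) == 0L) return(empty)
  data.frame(id = sprintf("contig%04d", seq_len(nrow(uni))),
             seq = uni$seq, length = nchar(uni$seq),
             mean_coverage = uni$coverage, row.names = NULL)
}

# Iterative tip removal and bubble popping on the k-mer count set.
clean_graph <- function(counts, k, max_rounds = 8L) {
  for (round in seq_len(max_rounds)) {
    env <- kmer_env(counts)
    uni <- build_unitigs(env, names(counts), k)
    changed <- FALSE

    # tips: dead end on one side, junction on the other, shorter than 2k
    tip <- (uni$in_first == 0L | uni$out_last == 0L) &
      (uni$in_first > 0L | uni$out_last > 0L) &
      nchar(uni$seq) < 2L * k
    if (any(tip)) {
      counts <- drop_unitig_kmers(counts, uni$seq[tip], k)
      changed <- TRUE
    } else {
      # bubbles: parallel unitigs with identical flanking junction nodes,
      # equal length, <= 2 substitutions apart; keep the deeper branch
      first_node <- substring(uni$seq, 1L, k - 1L)
      last_node <- substring(uni$seq, nchar(uni$seq) - k + 2L, nchar(uni$seq))
      key <- paste(first_node, last_node, nchar(uni$seq))
      dupk <- key[duplicated(key)]
      drop <- character()
      for (kk in unique(dupk)) {
        grp <- which(key == kk)
        grp <- grp[order(-uni$coverage[grp])]
        keep <- uni$seq[grp[1L]]
        for (g in grp[-1L]) {
          if (hamming(keep, uni$seq[g]) <= 2) drop <- c(drop, uni$seq[g])
        }
      }
      if (length(drop)) {
        counts <- drop_unitig_kmers(counts, drop, k)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  counts
}

# ---- map-back quality control ----------------------------------------------

# k-mer position index over contigs: kmer -> list of (contig index, position)
contig_index <- function(contigs, k) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_len(nrow(contigs))) {
    s <- contigs$seq[ci]
    kms <- seq_kmers(s, k)
    for (p in seq_along(kms)) {
      cur <- get0(kms[p], envir = env, inherits = FALSE)
      assign(kms[p], rbind(cur, c(ci, p)), envir = env)
    }
  }
  env
}

# Seed-and-verify a single mate against the contig index. Returns the best
# placement (contig, start, strand, identity, overlap) or NULL. As in a
# local aligner, identity is computed over the read/contig overlap (bases
# hanging off a contig end are soft-clipped); placements must overlap the
# contig over at least `min_overlap_frac` of the read to count at all.
place_mate <- function(mate, contigs, idx, k, min_overlap_frac = 0.6) {
  best <- NULL
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) mate else revcomp(mate)
    n <- nchar(s)
    if (n < k) next
    min_overlap <- max(k, as.integer(floor(min_overlap_frac * n)))
    offs <- unique(c(seq(1L, n - k + 1L, by = max(1L, k %/% 2L)), n - k + 1L))
    seen <- character()
    for (o in offs) {
      seed <- substring(s, o, o + k - 1L)
      if (seed %in% seen) next
      seen <- c(seen, seed)
      hits <- get0(seed, envir = idx, inherits = FALSE)
      if (is.null(hits)) next
      for (h in seq_len(nrow(hits))) {
        ci <- hits[h, 1L]; pos <- hits[h, 2L]
        start <- pos - o + 1L
        ov <- ungapped_identity(s, contigs$seq[ci], start)
        if (ov$overlap < min_overlap) next
        if (is.null(best) || ov$identity > best$identity) {
          best <- list(contig = ci, start = start, strand = strand,
                       identity = ov$identity, overlap = ov$overlap)
        }
      }
      if (!is.null(best) && best$identity == 1) return(best)
    }
  }
  best
}

# Ungapped identity over the read/contig overlap at offset `start` (1-based
# on the contig; may be <= 0 or run past the end --- those bases are
# soft-clipped and excluded from the denominator).
ungapped_identity <- function(read, contig, start) {
  n <- nchar(read); cl <- nchar(contig)
  lo <- max(1L, start); hi <- min(cl, start + n - 1L)
  if (hi < lo) return(list(identity = 0, overlap = 0L))
  rpart <- substring(read, lo - start + 1L, hi - start + 1L)
  cpart <- substring(contig, lo, hi)
  m <- sum(strsplit(rpart, "", fixed = TRUE)[[1]] == strsplit(cpart, "", fixed = TRUE)[[1]])
  list(identity = m / (hi - lo + 1L), overlap = hi - lo + 1L)
}

#' Map read pairs back to their assembly
#'
#' Quality control mirroring the map-back step of a short-read aligner: a
#' pair counts as properly mapped when both mates place on the same contig
#' (k-mer seeded, ungapped verification with soft-clipping at contig ends)
#' at `min_identity` or better over the aligned portion, in opposing
#' orientations, with an implied fragment length inside the configured
#' shearing range widened by 50 bp on each side.
#'
#' @param pairs Read-pair table.
#' @param contigs Contig table from [assemble_reads()].
#' @param min_identity Minimum per-mate identity.
#' @param config A [pipeline_config()] (supplies `fragment_len_range` and
#'   the seeding k-mer size).
#' @return List of class `mapback_report`: `reads_total`, `reads_mapped`,
#'   `mapped_fraction`.
#' @export
map_back <- function(pairs, contigs, min_identity = 0.9,
                     config = pipeline_config()) {
  if (is.null(contigs) || nrow(contigs) == 0L)
    stop_format("map_back: empty contig set, nothing to map against")
  k <- config$kmer_size
  idx <- contig_index(contigs, k)
  lo <- config$fragment_len_range[1] - 50L
  hi <- config$fragment_len_range[2] + 50L
  n <- nrow(pairs)
  mapped <- 0L
  for (i in seq_len(n)) {
    p1 <- place_mate(pairs$seq1[i], contigs, idx, k)
    if (is.null(p1) || p1$identity < min_identity) next
    p2 <- place_mate(pairs$seq2[i], contigs, idx, k)
    if (is.null(p2) || p2$identity < min_identity) next
    if (p1$contig != p2$contig) next
    if (p1$strand == p2$strand) next
    ends <- c(p1$start, p1$start + nchar(pairs$seq1[i]) - 1L,
              p2$start, p2$start + nchar(pairs$seq2[i]) - 1L)
    insert <- max(ends) - min(ends) + 1L
    if (insert >= lo && insert <= hi) mapped <- mapped + 1L
  }
  structure(list(reads_total = n, reads_mapped = mapped,
                 mapped_fraction = if (n > 0L) mapped / n else NA_real_),
            class = "mapback_report")
}

#' @export
print.mapback_report <- function(x, ...) {
  cat(sprintf("map-back: %d / %d pairs properly mapped (%.1f%%)\n",
              x$reads_mapped, x$reads_total, 100 * x$mapped_fraction))
  invisible(x)
}

#' Contig length histogram
#'
#' Cumulative length distribution of an assembly, the funnel-plot view used
#' to spot the ~710 bp barcode bottleneck: sequences much longer than the
#' theoretical primer-to-primer product are assembly artefacts.
#'
#' @param contigs Contig table from [assemble_reads()].
#' @return `data.frame` with columns `length`, `count`, `cumulative_bp`,
#'   sorted by length; total cumulative bp equals the summed contig lengths.
#' @export
length_histogram <- function(contigs) {
  if (is.null(contigs) || nrow(contigs) == 0L) {
    return(data.frame(length = integer(), count = integer(),
                      cumulative_bp = integer()))
  }
  tab <- table(contigs$length)
  len <- as.integer(names(tab))
  cnt <- as.integer(tab)
  ord <- order(len)
  len <- len[ord]; cnt <- cnt[ord]
  data.frame(length = len, count = cnt,
             cumulative_bp = cumsum(len * cnt))
}
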