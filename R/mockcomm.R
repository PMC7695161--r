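#' Primer pairs and the Folmer COI primers
#'
#' `primer_pair()` builds a validated primer pair for in-silico PCR;
#' `folmer_primers()` returns the universal LCO1490/HCO2198 pair whose
#' primer-to-primer product is the ~710 bp animal COI barcode.
#'
#' @param forward,reverse Primer sequences, 5'->3', 18--30 bp.
#' @param max_mismatch Substitution mismatches tolerated per binding site
#'   outside the 3' clamp. The default of 3 mimics the cross-taxon tolerance
#'   of a degenerate universal primer.
#' @param three_prime_clamp Number of 3'-terminal bases that must match
#'   exactly for extension to occur.
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 3L,
                        three_prime_clamp = 3L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 18L || nchar(p) > 30L)
      stop_format("primers must be 18--30 bp (got %d bp)", nchar(p))
  }
  if (three_prime_clamp > min(nchar(forward), nchar(reverse)))
    stop_format("3' clamp longer than a primer")
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch),
                 three_prime_clamp = as.integer(three_prime_clamp)),
            class = "primer_pair")
}

#' @rdname primer_pair
#' @export
folmer_primers <- function(max_mismatch = 3L, three_prime_clamp = 3L) {
  primer_pair(forward = "GGTCAACAAATCATAAAGATATTGG",
              reverse = "TAAACTTCAGGGTGACCAAAAAATCA",
              max_mismatch = max_mismatch,
              three_prime_clamp = three_prime_clamp)
}

#' Evolve a taxonomy-structured reference database
#'
#' Simulates a set of full-length COI reference records by substitution-only
#' mutation down a balanced taxonomic tree. One random ancestral sequence is
#' built per run (random padding, forward primer site, random barcode insert,
#' reverse-complemented reverse primer site, random padding).
#' `divergence_per_rank[r]` is the expected pairwise divergence between two
#' leaves whose lineages first differ at rank r: two congeneric species sit
#' at the species-level divergence, two phyla at the phylum-level one. Edge
#' mutation rates are derived from successive differences of this vector, so
#' it must be strictly decreasing toward species. The defaults follow
#' typical COI divergence structure (~3% between congeneric species up to
#' ~30% between phyla). Primer-binding regions mutate at a strongly reduced
#' rate and the 3' clamp bases not at all (universal primers target
#' conserved sites), so in-silico PCR succeeds community-wide.
#'
#' @param n_phyla Number of phyla.
#' @param per_rank_fanout Integer vector of length 5: children per node at
#'   class, order, family, genus and species level.
#' @param divergence_per_rank Named (or ordered phylum..species) numeric
#'   vector of per-rank divergence increments, strictly decreasing with
#'   depth and all positive.
#' @param seed Integer RNG seed; identical seeds give identical databases.
#' @param insert_len Length of the inter-primer barcode insert (bp).
#' @param pad_len Flanking padding per side (bp); the total record length is
#'   `2 * pad_len + nchar(fwd) + insert_len + nchar(rev)` and must be >= 800.
#' @param primers A [primer_pair()]; defaults to the Folmer pair.
#' @param primer_rate_factor Multiplier (< 1) applied to the mutation rate
#'   inside primer-binding regions.
#' @return A [ref_db()] with complete six-rank lineages.
#' @export
evolve_references <- function(n_phyla = 2L,
                              per_rank_fanout = c(class = 1L, order = 1L,
                                                  family = 1L, genus = 1L,
                                                  species = 1L),
                              divergence_per_rank = c(phylum = 0.30,
                                                      class = 0.20,
                                                      order = 0.14,
                                                      family = 0.10,
                                                      genus = 0.06,
                                                      species = 0.03),
                              seed = 1L,
                              insert_len = 659L,
                              pad_len = 60L,
                              primers = folmer_primers(),
                              primer_rate_factor = 0.05) {
  if (length(per_rank_fanout) != 5L || any(per_rank_fanout < 1L))
    stop_format("per_rank_fanout must give >= 1 children at each of the 5 sub-phylum ranks")
  d <- as.numeric(divergence_per_rank)
  if (length(d) != 6L) stop_format("divergence_per_rank must have 6 entries (phylum..species)")
  if (any(d <= 0)) stop_format("degenerate divergence: all per-rank divergences must be > 0")
  if (any(diff(d) >= 0))
    stop_format("divergence_per_rank must strictly decrease from phylum to species")
  # per-edge rates: two leaves splitting at rank r accumulate, on the two
  # branches together, 2 * sum(edge_rate[r:6]) = divergence_per_rank[r]
  edge_rate <- c(d[-6L] - d[-1L], d[6L]) / 2
  fwd <- primers$forward; rev_rc <- revcomp(primers$reverse)
  total_len <- 2L * pad_len + nchar(fwd) + insert_len + nchar(rev_rc)
  if (total_len < 800L)
    stop_format("reference length %d < 800 bp; increase pad_len or insert_len", total_len)

  withr::with_seed(seed, {
    root <- paste0(random_dna(pad_len), fwd, random_dna(insert_len),
                   rev_rc, random_dna(pad_len))
    # per-site rate mask protecting primer-binding regions; the 3' clamp
    # bases are held invariant (a clamp mismatch would abort extension)
    fwd_pos <- seq(pad_len + 1L, pad_len + nchar(fwd))
    rev_pos <- seq(pad_len + nchar(fwd) + insert_len + 1L,
                   pad_len + nchar(fwd) + insert_len + nchar(rev_rc))
    rate_mask <- rep(1, total_len)
    rate_mask[c(fwd_pos, rev_pos)] <- primer_rate_factor
    clamp <- primers$three_prime_clamp
    rate_mask[c(utils::tail(fwd_pos, clamp), utils::head(rev_pos, clamp))] <- 0

    grow <- function(seq, depth, label_prefix, lineage) {
      if (depth > 6L) {
        return(list(list(seq = seq, lineage = taxon_path(lineage))))
      }
      fan <- if (depth == 1L) n_phyla else per_rank_fanout[depth - 1L]
      out <- list()
      for (i in seq_len(fan)) {
        name <- if (depth == 1L) sprintf("P%02d", i)
                else sprintf("%s%s%d", label_prefix,
                             toupper(substr(tax_ranks()[depth], 1L, 1L)), i)
        child <- mutate_seq(seq, edge_rate[depth] * rate_mask)
        out <- c(out, grow(child, depth + 1L, name, c(lineage, name)))
      }
      out
    }
    leaves <- grow(root, 1L, "", character(0))
    ids <- sprintf("ref%03d", seq_along(leaves))
    seqs <- setNames(vapply(leaves, `[[`, character(1), "seq"), ids)
    taxonomy <- setNames(lapply(leaves, `[[`, "lineage"), ids)
    ref_db(seqs, taxonomy)
  })
}

#' Sample a community abundance profile
#'
#' Log-normal relative abundances around equimolar, normalised to sum to 1.
#' The default spread is mild because the emulated protocol pools amplicons
#' at equimolar concentration; `sdlog` controls residual pipetting and
#' amplification noise.
#'
#' @param ids Reference identifiers.
#' @param seed Integer RNG seed.
#' @param sdlog Log-scale standard deviation of the abundance draw.
#' @return Named numeric vector of positive weights summing to 1.
#' @export
community_profile <- function(ids, seed = 1L, sdlog = 0.35) {
  stopifnot(length(ids) > 0L)
  withr::with_seed(seed, {
    w <- rlnorm(length(ids), meanlog = 0, sdlog = sdlog)
    setNames(w / sum(w), ids)
  })
}

#' In-silico PCR
#'
#' Finds every primer-to-primer product on a template: a forward-primer
#' binding site followed on the same strand by the reverse complement of a
#' reverse-primer binding site, inclusive of both primer regions. Binding
#' tolerates up to `max_mismatch` substitutions but none inside the 3'
#' clamp. Both strands are scanned; products are reported in the orientation
#' in which the forward primer is at the 5' end.
#'
#' @param template DNA string (IUPAC).
#' @param primers A [primer_pair()].
#' @return Character vector of amplicon sequences (empty when no site).
#' @export
in_silico_pcr <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- toupper(template)
  products <- c(pcr_one_strand(template, primers),
                pcr_one_strand(revcomp(template), primers))
  unique(products)
}

pcr_one_strand <- function(template, primers) {
  fwd <- primers$forward
  rrc <- revcomp(primers$reverse)
  clamp <- primers$three_prime_clamp
  subj <- Biostrings::DNAString(template)
  hit_ranges <- function(pattern) {
    m <- Biostrings::matchPattern(pattern, subj,
                                  max.mismatch = primers$max_mismatch,
                                  with.indels = FALSE)
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m))
  }
  f <- hit_ranges(fwd)
  r <- hit_ranges(rrc)
  if (nrow(f) == 0L || nrow(r) == 0L) return(character())
  # 3' clamp must be exact: last bases of fwd; first bases of revcomp(rev)
  f_ok <- substring(template, f$end - clamp + 1L, f$end) ==
    substring(fwd, nchar(fwd) - clamp + 1L, nchar(fwd))
  r_ok <- substring(template, r$start, r$start + clamp - 1L) ==
    substring(rrc, 1L, clamp)
  f <- f[f_ok, , drop = FALSE]
  r <- r[r_ok, , drop = FALSE]
  out <- character()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      if (r$start[j] > f$end[i]) {
        out <- c(out, substring(template, f$start[i], r$end[j]))
      }
    }
  }
  out
}

#' Shear amplicons into random fragments
#'
#' Emulates sonication: amplicons are sampled proportional to their
#' abundance weights, fragment lengths are uniform over `frag_range`
#' (clipped to the amplicon length) and start positions are uniform over
#' all valid positions. An amplicon shorter than the minimum fragment
#' length contributes whole-length fragments, flagged in the output.
#'
#' @param amplicons Named character vector of amplicon sequences.
#' @param frag_range Integer pair, fragment length range in bp.
#' @param total_fragments Number of fragments to draw.
#' @param seed Integer RNG seed.
#' @param weights Optional named abundance weights (defaults to uniform).
#' @return `data.frame` with columns `amp_id`, `start`, `end` (1-based,
#'   inclusive, amplicon coordinates), `seq`, `whole`.
#' @export
shear_fragments <- function(amplicons, frag_range, total_fragments, seed = 1L,
                            weights = NULL) {
  stopifnot(length(amplicons) > 0L)
  if (is.null(names(amplicons)))
    names(amplicons) <- sprintf("amp%03d", seq_along(amplicons))
  if (is.null(weights)) weights <- rep(1, length(amplicons))
  if (!is.null(names(weights))) weights <- weights[names(amplicons)]
  stopifnot(all(weights > 0), length(weights) == length(amplicons))
  lo <- as.integer(frag_range[1]); hi <- as.integer(frag_range[2])
  stopifnot(lo >= 1L, lo <= hi)
  n <- as.integer(total_fragments)
  if (n == 0L) {
    return(data.frame(amp_id = character(), start = integer(),
                      end = integer(), seq = character(), whole = logical()))
  }
  amp_len <- nchar(amplicons)
  withr::with_seed(seed, {
    idx <- sample.int(length(amplicons), n, replace = TRUE,
                      prob = weights / sum(weights))
    la <- amp_len[idx]
    whole <- la < lo
    hi_i <- pmin(hi, la)
    flen <- lo + floor(runif(n) * (hi_i - lo + 1L))
    flen[whole] <- la[whole]
    start <- 1L + floor(runif(n) * (la - flen + 1L))
    end <- start + flen - 1L
    data.frame(amp_id = names(amplicons)[idx],
               start = as.integer(start), end = as.integer(end),
               seq = substring(amplicons[idx], start, end),
               whole = whole, row.names = NULL)
  })
}

# Apply i.i.d. substitution errors at `rate` to a character vector of reads.
add_read_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  all <- unlist(ch, use.names = FALSE)
  hit <- which(runif(length(all)) < rate)
  if (length(hit)) {
    bi <- match(all[hit], DNA_BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    all[hit] <- DNA_BASES[((bi - 1L + shift) %% 4L) + 1L]
  }
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(all, grp), paste, character(1), collapse = "")
}

#' Generate paired-end reads from fragments
#'
#' Emulates 2x`read_len` bp paired-end sequencing: mate 1 is the first
#' `read_len` bases of each fragment, mate 2 the reverse complement of the
#' last `read_len` bases. Substitution errors are i.i.d. at
#' `sub_error_rate`; quality strings encode the error rate used
#' (Phred+33, capped at Q40 for error-free reads). A fragment shorter than
#' `read_len` yields full-fragment mates.
#'
#' @param fragments Fragment table from [shear_fragments()].
#' @param read_len Read length in bp.
#' @param sub_error_rate Per-base substitution error probability in `[0, 0.5)`.
#' @param seed Integer RNG seed.
#' @return Read-pair `data.frame` with columns `id`, `seq1`, `qual1`,
#'   `seq2`, `qual2` and truth columns `src_id`, `frag_start`, `frag_end`.
#' @export
sequence_reads <- function(fragments, read_len = 150L, sub_error_rate = 0,
                           seed = 1L) {
  stopifnot(sub_error_rate >= 0, sub_error_rate < 0.5)
  n <- nrow(fragments)
  if (n == 0L) {
    return(data.frame(id = character(), seq1 = character(), qual1 = character(),
                      seq2 = character(), qual2 = character(),
                      src_id = character(), frag_start = integer(),
                      frag_end = integer()))
  }
  flen <- nchar(fragments$seq)
  m1 <- substring(fragments$seq, 1L, pmin(read_len, flen))
  m2 <- revcomp(substring(fragments$seq, pmax(1L, flen - read_len + 1L), flen))
  withr::with_seed(seed, {
    m1 <- add_read_errors(m1, sub_error_rate)
    m2 <- add_read_errors(m2, sub_error_rate)
  })
  q <- if (sub_error_rate <= 0) 40L
       else as.integer(max(2L, min(40L, round(-10 * log10(sub_error_rate)))))
  qc <- rawToChar(as.raw(q + 33L))
  data.frame(id = sprintf("read%06d", seq_len(n)),
             seq1 = m1, qual1 = strrep(qc, nchar(m1)),
             seq2 = m2, qual2 = strrep(qc, nchar(m2)),
             src_id = fragments$amp_id,
             frag_start = fragments$start, frag_end = fragments$end,
             row.names = NULL)
}

#' Simulate a full mock community sequencing run
#'
#' Runs the whole wet-lab analogue: in-silico PCR of every reference with
#' the configured primers, log-normal community abundances, random shearing
#' to the configured fragment range, and error-bearing paired-end reads.
#' Mean coverage is interpreted community-wide: the number of fragments is
#' `coverage * total amplicon length / mean fragment length`.
#'
#' @param refs A [ref_db()] of templates (full six-rank lineages).
#' @param config A [pipeline_config()].
#' @param coverage Target mean fragment coverage per amplicon base.
#' @param sub_error_rate Per-base substitution error rate of the sequencer.
#' @param seed Integer RNG seed (sub-stages derive fixed offsets from it).
#' @param primers A [primer_pair()].
#' @param profile Optional abundance profile; defaults to
#'   [community_profile()] over the amplified references.
#' @param profile_sdlog Spread passed to [community_profile()].
#' @return List with elements `pairs` (read-pair table with truth columns),
#'   `amplicons` (named by source reference id), `profile`, `fragments`,
#'   and `refs`.
#' @export
simulate_community <- function(refs, config = pipeline_config(),
                               coverage = 30, sub_error_rate = 0.005,
                               seed = config$rng_seed,
                               primers = folmer_primers(),
                               profile = NULL, profile_sdlog = 0.35) {
  stopifnot(inherits(refs, "ref_db"))
  amps <- character(0)
  for (id in names(refs$seqs)) {
    prod <- in_silico_pcr(refs$seqs[[id]], primers)
    if (length(prod) == 0L) {
      warning(sprintf("no amplicon for reference '%s'; dropped from community", id))
      next
    }
    amps[[id]] <- prod[[1L]]
  }
  if (length(amps) == 0L) stop_format("no reference amplified")
  if (is.null(profile)) {
    profile <- community_profile(names(amps), seed = seed, sdlog = profile_sdlog)
  }
  mean_frag <- mean(config$fragment_len_range)
  n_frag <- as.integer(ceiling(coverage * sum(nchar(amps)) / mean_frag))
  frags <- shear_fragments(amps, config$fragment_len_range, n_frag,
                           seed = seed + 1L, weights = profile)
  pairs <- sequence_reads(frags, read_len = config$read_len,
                          sub_error_rate = sub_error_rate, seed = seed + 2L)
  list(pairs = pairs, amplicons = amps, profile = profile,
       fragments = frags, refs = refs)
}

#' Write a simulated community to disk
#'
#' Emits the paired FASTQ files, reference FASTA, taxonomy TSV, the
#' abundance profile and the read truth table.
#'
#' @param sim Result of [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fastq1 = file.path(dir, "reads_1.fastq"),
             fastq2 = file.path(dir, "reads_2.fastq"),
             refs = file.path(dir, "references.fasta"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             profile = file.path(dir, "profile.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fastq_pairs(sim$pairs, paths[["fastq1"]], paths[["fastq2"]])
  write_ref_db(sim$refs, paths[["refs"]], paths[["taxonomy"]])
  write.table(data.frame(ref_id = names(sim$profile), weight = sim$profile),
              paths[["profile"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$pairs[, c("id", "src_id", "frag_start", "frag_end")],
              paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
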