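# End-to-end orchestration: trim -> assemble -> map-back QC -> length filter
# -> dereplicate -> chimera screen -> cluster -> consensus -> two-mode search
# -> LCA -> summaries, with a reproducibility manifest.

stage_log <- function(stage, msg, quiet) {
  if (!quiet) message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full shear-and-reassemble pipeline
#'
#' Executes every stage of the barcode-reconstruction pipeline on a pair of
#' FASTQ files against a taxonomy-annotated reference database, writing all
#' intermediate tables plus a JSON manifest (configuration, seed, input
#' checksums and per-stage record counts) to `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param fastq1,fastq2 Paired FASTQ paths.
#' @param ref_fasta,ref_taxonomy Reference database paths (FASTA + TSV).
#' @param outdir Output directory (created if needed).
#' @param min_quality,adapter,min_len Trimming parameters (see
#'   [trim_reads()]).
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, fastq1, fastq2, ref_fasta, ref_taxonomy,
                         outdir, min_quality = 20L, adapter = NULL,
                         min_len = 50L, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  refdb <- read_ref_db(ref_fasta, ref_taxonomy)
  pairs <- read_fastq_pairs(fastq1, fastq2)
  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    inputs = as.list(tools::md5sum(c(fastq1, fastq2, ref_fasta, ref_taxonomy))),
    counts = list(raw_pairs = nrow(pairs)))

  stage_log("trim", sprintf("%d raw pairs", nrow(pairs)), quiet)
  trimmed <- trim_reads(pairs, min_quality = min_quality, adapter = adapter,
                        min_len = max(min_len, config$kmer_size))
  manifest$counts$trimmed_pairs <- nrow(trimmed)

  stage_log("assemble", sprintf("%d trimmed pairs, k = %d", nrow(trimmed),
                                config$kmer_size), quiet)
  contigs <- assemble_reads(trimmed, k = config$kmer_size,
                            min_contig_len = config$min_contig_len)
  manifest$counts$contigs <- nrow(contigs)
  write_fasta(setNames(contigs$seq, contigs$id), file.path(outdir, "contigs.fasta"))
  hist <- length_histogram(contigs)
  write.table(hist, file.path(outdir, "length_histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  stage_log("map-back", sprintf("%d contigs", nrow(contigs)), quiet)
  mb <- map_back(trimmed, contigs, config = config)
  write.table(data.frame(reads_total = mb$reads_total,
                         reads_mapped = mb$reads_mapped,
                         mapped_fraction = mb$mapped_fraction),
              file.path(outdir, "mapback.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest$mapback_fraction <- mb$mapped_fraction

  lf <- length_filter(contigs, config$max_assembly_len)
  manifest$counts$contigs_kept <- nrow(lf$kept)
  manifest$counts$contigs_removed <- nrow(lf$removed)
  write_fasta(setNames(lf$kept$seq, lf$kept$id), file.path(outdir, "contigs_kept.fasta"))
  if (nrow(lf$removed) > 0L)
    write_fasta(setNames(lf$removed$seq, lf$removed$id),
                file.path(outdir, "contigs_removed.fasta"))

  stage_log("dereplicate", sprintf("%d contigs kept", nrow(lf$kept)), quiet)
  feats <- dereplicate(lf$kept$seq)
  manifest$counts$unique_features <- nrow(feats)

  stage_log("chimera-screen", sprintf("%d features", nrow(feats)), quiet)
  chim <- flag_chimeras(feats, refdb, config = config)
  manifest$counts$features_clean <- nrow(chim$clean)
  manifest$counts$features_flagged <- nrow(chim$flagged)

  stage_log("cluster", sprintf("identity %.2f", config$cluster_identity), quiet)
  clusters <- cluster_greedy(chim$clean, identity = config$cluster_identity)
  manifest$counts$clusters <- length(clusters)
  cluster_table(clusters, file.path(outdir, "clusters.tsv"))
  consensus <- vapply(clusters, `[[`, character(1), "consensus")
  names(consensus) <- sprintf("OTU%04d", seq_along(consensus))
  if (length(consensus))
    write_fasta(consensus, file.path(outdir, "consensus.fasta"))

  stage_log("search", sprintf("%d consensus sequences, both modes",
                              length(consensus)), quiet)
  res <- list()
  for (mode in c("high-identity", "sensitive")) {
    r <- assign_queries(consensus, refdb, mode = mode, config = config)
    res[[mode]] <- r
    tag <- if (mode == "high-identity") "megablast_like" else "blastn_like"
    if (!is.null(r$hits))
      write.table(r$hits, file.path(outdir, sprintf("hits_%s.tsv", tag)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(assignments_table(r$assignments),
                file.path(outdir, sprintf("assignments_%s.tsv", tag)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  overlap <- compare_modes(res[["high-identity"]]$assignments,
                           res[["sensitive"]]$assignments)
  manifest$mode_overlap <- overlap[c("n_intersection", "frac_a_not_b", "frac_b_not_a")]

  stage_log("summaries", "rank table and diversity indices", quiet)
  assignments <- res[["sensitive"]]$assignments
  rs <- rank_summary(assignments)
  write.table(rs, file.path(outdir, "rank_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sizes <- vapply(clusters, `[[`, integer(1), "total_size")
  if (length(sizes) > 0L && sum(sizes) > 0) {
    div <- diversity_indices(sizes)
    write.table(as.data.frame(unclass(div)), file.path(outdir, "diversity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$diversity <- unclass(div)
  }
  manifest$counts$assigned <- sum(!vapply(assignments, function(a)
    a$assigned_rank %in% c("unknown", "unknown-eukaryotic"), logical(1)))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run the validation campaigns
#'
#' The two quality-assurance procedures applied to the assignment machinery:
#' half-split concordance on pure (non-chimeric) simulated queries drawn
#' from the reference set, and the chimera injection test on synthetic
#' cross-class chimeras.
#'
#' @param config A [pipeline_config()].
#' @param refdb A [ref_db()].
#' @param outdir Output directory.
#' @param n_chimeras Number of chimeras to inject.
#' @param n_pure Number of pure queries for the concordance test (mutated
#'   copies of reference sequences).
#' @param mutation_rate Per-site divergence applied to the pure queries.
#' @param seed Integer RNG seed.
#' @param quiet Suppress progress messages.
#' @return List with `concordance` (a `concordance_report`) and `chimera`
#'   (result of [chimera_rank_test()]), invisibly; reports are written as
#'   TSV to `outdir`.
#' @export
run_validation <- function(config, refdb, outdir, n_chimeras = 100L,
                           n_pure = 50L, mutation_rate = 0.01,
                           seed = config$rng_seed, quiet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_log("validate", sprintf("%d pure queries at %.1f%% mutation", n_pure,
                                100 * mutation_rate), quiet)
  pure <- withr::with_seed(seed, {
    src <- sample(names(refdb$seqs), n_pure, replace = TRUE)
    vapply(src, function(id) mutate_seq(refdb$seqs[[id]], mutation_rate),
           character(1))
  })
  conc <- half_concordance(pure, refdb, config = config)
  write.table(as.data.frame(unclass(conc)),
              file.path(outdir, "half_concordance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  stage_log("validate", sprintf("%d injected chimeras", n_chimeras), quiet)
  chims <- make_chimeras(refdb, n = n_chimeras, seed = seed + 1L,
                         max_len = config$max_assembly_len)
  ct <- chimera_rank_test(chims, refdb, config = config)
  write.table(ct$table, file.path(outdir, "chimera_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(n_chimeras = length(chims), n_unknown = ct$n_unknown),
              file.path(outdir, "chimera_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(concordance = conc, chimera = ct))
}
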