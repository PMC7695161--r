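#' Pipeline configuration
#'
#' Bundles the fixed parameters of the shear-and-reassemble pipeline. The
#' defaults encode the study design this package emulates: amplicons sheared
#' to 250--300 bp and sequenced with 2x150 bp paired-end chemistry; assembled
#' barcodes longer than 712 bp (the theoretical LCO1490/HCO2198 product is
#' ~710 bp) treated as artefacts; OTUs at 98% identity; database hits kept at
#' >= 70% identity and e-value <= 1e-5 with the four best matches retained.
#'
#' @param fragment_len_range Integer pair, sheared fragment length range (bp).
#' @param read_len Read length in bp for each mate.
#' @param max_assembly_len Maximum plausible barcode length (bp); longer
#'   assemblies are filtered as artefacts.
#' @param cluster_identity OTU clustering identity threshold, in (0, 1].
#' @param min_hit_identity Minimum alignment identity for a database hit.
#' @param max_evalue Maximum e-value for a database hit.
#' @param top_hits Number of best hits retained per query.
#' @param kmer_size Odd k-mer size for the assembler.
#' @param min_contig_len Minimum contig length emitted by the assembler (bp).
#' @param rng_seed Integer seed controlling all randomised stages.
#' @return An object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$max_assembly_len
#' @export
pipeline_config <- function(fragment_len_range = c(250L, 300L),
                            read_len = 150L,
                            max_assembly_len = 712L,
                            cluster_identity = 0.98,
                            min_hit_identity = 0.70,
                            max_evalue = 1e-5,
                            top_hits = 4L,
                            kmer_size = 31L,
                            min_contig_len = 200L,
                            rng_seed = 1L) {
  cfg <- list(
    fragment_len_range = as.integer(fragment_len_range),
    read_len = as.integer(read_len),
    max_assembly_len = as.integer(max_assembly_len),
    cluster_identity = as.numeric(cluster_identity),
    min_hit_identity = as.numeric(min_hit_identity),
    max_evalue = as.numeric(max_evalue),
    top_hits = as.integer(top_hits),
    kmer_size = as.integer(kmer_size),
    min_contig_len = as.integer(min_contig_len),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (length(fragment_len_range) != 2L || any(fragment_len_range <= 0L) ||
        fragment_len_range[1] > fragment_len_range[2])
      stop_format("fragment_len_range must be a positive pair low <= high")
    if (read_len <= 0L || max_assembly_len <= 0L || min_contig_len <= 0L)
      stop_format("all lengths must be positive")
    for (id in c(cluster_identity, min_hit_identity))
      if (!(id > 0 && id <= 1))
        stop_format("identity thresholds must lie in (0, 1]")
    if (max_evalue <= 0) stop_format("max_evalue must be positive")
    if (top_hits < 1L) stop_format("top_hits must be >= 1")
    if (kmer_size %% 2L == 0L) stop_format("kmer_size must be odd")
    if (kmer_size >= 2L * read_len)
      stop_format("kmer_size must be < 2 * read_len")
  })
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("shear-and-reassemble pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = "-")))
  invisible(x)
}

#' Write / read a pipeline configuration
#'
#' Plain `key=value` text serialisation; `read_config()` rebuilds the object
#' through [pipeline_config()], so out-of-range values are rejected on read.
#'
#' @param config A `pipeline_config` object.
#' @param path File path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()` its
#'   input, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(nm) {
    sprintf("%s=%s", nm, paste(format(config[[nm]], scientific = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop_format("malformed config line: %s", lines[bad][1])
  vals <- lapply(kv, function(p) as.numeric(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) stop_format("unknown config key: %s", unknown[1])
  do.call(pipeline_config, vals)
}
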