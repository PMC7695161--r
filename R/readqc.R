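#' Quality-trim and adapter-clip read pairs
#'
#' Minimal quality control ahead of assembly: leading and trailing bases
#' below `min_quality` are removed from each mate, any read suffix that
#' exactly matches a prefix of the adapter over at least 8 bp is clipped,
#' and pairs where either trimmed mate falls below `min_len` are dropped
#' whole (both mates or neither, which keeps the assembler contract simple).
#' Surviving bases are never altered: every output read is a substring of
#' its input read, and the operation is idempotent.
#'
#' @param pairs Read-pair table (see [read_fastq_pairs()]); extra columns
#'   such as simulation truth are carried through.
#' @param min_quality Minimum Phred score kept at the read ends.
#' @param adapter Adapter sequence to clip from read 3' ends, or `NULL`.
#' @param min_len Minimum surviving mate length in bp.
#' @return The filtered read-pair table.
#' @export
trim_reads <- function(pairs, min_quality = 20L, adapter = NULL,
                       min_len = 50L) {
  stopifnot(min_quality >= 0L, min_len >= 1L)
  if (nrow(pairs) == 0L) return(pairs)
  trim1 <- trim_mate(pairs$seq1, pairs$qual1, min_quality, adapter)
  trim2 <- trim_mate(pairs$seq2, pairs$qual2, min_quality, adapter)
  keep <- nchar(trim1$seq) >= min_len & nchar(trim2$seq) >= min_len
  out <- pairs[keep, , drop = FALSE]
  out$seq1 <- trim1$seq[keep];  out$qual1 <- trim1$qual[keep]
  out$seq2 <- trim2$seq[keep];  out$qual2 <- trim2$qual[keep]
  rownames(out) <- NULL
  out
}

trim_mate <- function(seqs, quals, min_quality, adapter) {
  n <- length(seqs)
  out_seq <- character(n); out_qual <- character(n)
  for (i in seq_len(n)) {
    s <- seqs[i]; q <- quals[i]
    # adapter clip: earliest position whose suffix exactly matches a prefix
    # of the adapter over >= 8 bp
    if (!is.null(adapter) && nchar(s) >= 8L) {
      len <- nchar(s)
      for (pos in seq_len(len - 7L)) {
        span <- len - pos + 1L
        if (substring(s, pos, len) == substring(adapter, 1L, span)) {
          s <- substring(s, 1L, pos - 1L)
          q <- substring(q, 1L, pos - 1L)
          break
        }
      }
    }
    # end-trimming by quality
    if (nchar(s) > 0L) {
      phred <- as.integer(charToRaw(q)) - 33L
      ok <- which(phred >= min_quality)
      if (length(ok) == 0L) {
        s <- ""; q <- ""
      } else {
        s <- substring(s, ok[1L], ok[length(ok)])
        q <- substring(q, ok[1L], ok[length(ok)])
      }
    }
    out_seq[i] <- s; out_qual[i] <- q
  }
  list(seq = out_seq, qual = out_qual)
}
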