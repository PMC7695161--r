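#' Read a FASTA file
#'
#' Thin validating wrapper over [Biostrings::readDNAStringSet()]. Identifiers
#' are the first whitespace-delimited token of each header and must be unique;
#' sequences are uppercased and must contain only IUPAC nucleotide codes
#' (which the DNA parser itself enforces).
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return Named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_format("FASTA format error in %s: %s", path, conditionMessage(e))
  )
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop_format("duplicate FASTA id '%s' in %s", ids[duplicated(ids)][1], path)
  seqs <- toupper(as.character(set))
  setNames(seqs, ids)
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Minimal strict 4-line FASTQ record reader returning id/seq/qual vectors.
read_fastq_file <- function(path) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  while (length(lines) > 0L && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop_format("FASTQ format error in %s: truncated record", path)
  n <- length(lines) %/% 4L
  if (n == 0L) return(data.frame(id = character(), seq = character(), qual = character()))
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(!startsWith(hdr, "@")) || any(!startsWith(plus, "+")))
    stop_format("FASTQ format error in %s: malformed record markers", path)
  if (any(nchar(seq) != nchar(qual)))
    stop_format("FASTQ format error in %s: sequence/quality length mismatch", path)
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seq)
  if (any(bad)) stop_format("FASTQ format error in %s: non-IUPAC character", path)
  id <- vapply(strsplit(substring(hdr, 2L), "\\s+"), `[[`, character(1), 1L)
  data.frame(id = id, seq = seq, qual = qual)
}

# Strip a trailing mate suffix (/1, /2, .1, .2, _1, _2) from read ids.
strip_mate_suffix <- function(id) sub("[/._][12]$", "", id)

#' Read paired FASTQ files
#'
#' Reads two parallel FASTQ files (Phred+33) into a read-pair table. The
#' files must contain the same number of records with matching identifiers
#' up to a mate suffix (`/1`, `/2` and similar).
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return A `data.frame` with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  m1 <- read_fastq_file(path1)
  m2 <- read_fastq_file(path2)
  if (nrow(m1) != nrow(m2))
    stop_format("pairing error: %d records in %s but %d in %s",
                nrow(m1), path1, nrow(m2), path2)
  id1 <- strip_mate_suffix(m1$id)
  id2 <- strip_mate_suffix(m2$id)
  if (!identical(id1, id2)) {
    bad <- which(id1 != id2)[1]
    stop_format("pairing error: unpaired id '%s' vs '%s' at record %d",
                m1$id[bad], m2$id[bad], bad)
  }
  data.frame(id = id1, seq1 = m1$seq, qual1 = m1$qual,
             seq2 = m2$seq, qual2 = m2$qual)
}

#' Write paired FASTQ files
#'
#' @param pairs Read-pair table as returned by [read_fastq_pairs()] or
#'   [sequence_reads()].
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  fmt <- function(id, mate, seq, qual) {
    as.vector(rbind(sprintf("@%s/%d", id, mate), seq, "+", qual))
  }
  writeLines(fmt(pairs$id, 1L, pairs$seq1, pairs$qual1), path1)
  writeLines(fmt(pairs$id, 2L, pairs$seq2, pairs$qual2), path2)
  invisible(c(path1, path2))
}
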