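#' @import methods
#' @importFrom stats median rbinom rlnorm runif setNames
#' @importFrom utils head read.delim write.table
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings, delegating to
#' [Biostrings::reverseComplement()] so IUPAC ambiguity codes are handled.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical orientation of DNA strings
#'
#' Returns, for each sequence, the lexicographically smaller of the sequence
#' and its reverse complement. Assembly and dereplication use this so that
#' strand, which is arbitrary for an assembled barcode, never affects results.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector in canonical orientation.
#' @export
canonical_orientation <- function(x) {
  if (length(x) == 0L) return(character())
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Uniform random DNA string(s); relies on the caller having seeded the RNG.
random_dna <- function(n_bases, n = 1L) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, n_bases, replace = TRUE), collapse = "")
  }, character(1))
}

# All k-mers of a single string (empty when shorter than k).
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1L), k:n)
}

# Per-site substitution mutation. `rate` may be a vector of per-site rates
# recycled to the sequence length (used to protect primer-binding regions).
mutate_seq <- function(s, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  rate <- rep_len(rate, n)
  hit <- which(runif(n) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# Hamming distance between equal-length strings (Inf when lengths differ).
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
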