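# Shared fixtures, built in code and memoised for the session.

.fx <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# 16-reference database: 2 phyla x 2 classes x 2 orders x 2 genera.
fx_refdb16 <- function() {
  fx_memo("refdb16", function()
    evolve_references(n_phyla = 2, per_rank_fanout = c(2, 2, 1, 2, 1), seed = 42))
}

# 10-species mock community spread over 5 phyla (2 classes each): the
# well-separated design used for assembly-facing checks.
fx_refdb10 <- function() {
  fx_memo("refdb10", function()
    evolve_references(n_phyla = 5, per_rank_fanout = c(2, 1, 1, 1, 1), seed = 7))
}

# Database dense at genus level (4 congeneric species per genus).
fx_refdb_dense <- function() {
  fx_memo("refdb_dense", function()
    evolve_references(n_phyla = 2, per_rank_fanout = c(1, 1, 1, 2, 4), seed = 19))
}

# Community of amplicons with provably disjoint insert k-mer spectra:
# independent random inserts behind shared primer sites. Verifies during
# construction that no 31-mer is shared between any two amplicons, so
# single-k assembly closure is achievable by construction.
fx_disjoint_amplicons <- function(n = 10L, k = 31L) {
  fx_memo(paste0("disjoint", n), function() {
    p <- folmer_primers()
    amps <- withr::with_seed(202, vapply(seq_len(n), function(i)
      paste0(p$forward, shearcoi:::random_dna(659), revcomp(p$reverse)),
      character(1)))
    names(amps) <- sprintf("amp%02d", seq_len(n))
    spectra <- lapply(amps, function(a)
      unique(c(shearcoi:::seq_kmers(a, k), shearcoi:::seq_kmers(revcomp(a), k))))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        stopifnot(length(intersect(spectra[[i]], spectra[[j]])) == 0L)
      }
    }
    amps
  })
}

# One deterministic ~710 bp amplicon (primer-to-primer product).
fx_amplicon <- function() {
  fx_memo("amplicon", function() {
    p <- folmer_primers()
    withr::with_seed(101, paste0(p$forward, shearcoi:::random_dna(659),
                                 revcomp(p$reverse)))
  })
}

# Error-free read pairs tiling an amplicon end to end at fixed stride.
# Each fragment is emitted twice so that even terminal k-mers are observed
# more than once and survive the assembler's singleton cut.
fx_tile_pairs <- function(amplicon, frag_len = 280L, stride = 5L,
                          read_len = 150L) {
  L <- nchar(amplicon)
  starts <- unique(c(seq(1L, L - frag_len + 1L, by = stride), L - frag_len + 1L))
  starts <- rep(starts, 2L)
  frags <- data.frame(amp_id = "amp", start = starts,
                      end = starts + frag_len - 1L,
                      seq = substring(amplicon, starts, starts + frag_len - 1L),
                      whole = FALSE)
  sequence_reads(frags, read_len = read_len, sub_error_rate = 0, seed = 1L)
}

# Mutated copy of a sequence at a fixed per-site substitution rate.
fx_mutate <- function(seq, rate, seed) {
  withr::with_seed(seed, shearcoi:::mutate_seq(seq, rate))
}

# A sequence carrying substitutions at every `step`-th position, so its
# longest exact run against the original is step - 1 bases.
fx_mutate_every <- function(seq, step, seed = 1L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  withr::with_seed(seed, {
    for (i in seq(step, length(chars), by = step)) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  })
  paste(chars, collapse = "")
}

# Small fully annotated taxonomy for LCA unit tests.
fx_insect_taxonomy <- function() {
  list(
    aedes_aegypti = taxon_path("Arthropoda", "Insecta", "Diptera", "Culicidae",
                               "Aedes", "Aedes aegypti"),
    aedes_albopictus = taxon_path("Arthropoda", "Insecta", "Diptera", "Culicidae",
                                  "Aedes", "Aedes albopictus"),
    culex_pipiens = taxon_path("Arthropoda", "Insecta", "Diptera", "Culicidae",
                               "Culex", "Culex pipiens"),
    drosophila = taxon_path("Arthropoda", "Insecta", "Diptera", "Drosophilidae",
                            "Drosophila", "Drosophila hydei"),
    danio = taxon_path("Chordata", "Actinopterygii", "Cypriniformes", "Danionidae",
                       "Danio", "Danio rerio")
  )
}

fake_hits <- function(subject_ids, scores = NULL, query_id = "q") {
  n <- length(subject_ids)
  data.frame(query_id = rep(query_id, n), subject_id = subject_ids,
             percent_identity = rep(0.95, n), align_len = rep(500L, n),
             raw_score = scores %||% seq(500, by = -1, length.out = n),
             evalue = rep(1e-20, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
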