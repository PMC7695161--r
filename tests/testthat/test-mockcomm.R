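# Mock-community generator: reference evolution, in-silico PCR, shearing,
# read simulation.

test_that("evolve_references respects tree shape and determinism", {
  one <- evolve_references(n_phyla = 1, per_rank_fanout = rep(1L, 5), seed = 3)
  expect_length(one, 1L)
  expect_length(one$taxonomy[[1]], 6L)
  expect_gte(nchar(one$seqs[[1]]), 800L)

  a <- evolve_references(n_phyla = 2, per_rank_fanout = c(2, 1, 1, 1, 1), seed = 5)
  b <- evolve_references(n_phyla = 2, per_rank_fanout = c(2, 1, 1, 1, 1), seed = 5)
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$taxonomy, b$taxonomy)

  expect_error(evolve_references(divergence_per_rank = c(0.3, 0.2, 0.14, 0.1, 0.06, 0),
                                 seed = 1), "degenerate")
  expect_error(evolve_references(divergence_per_rank = c(0.3, 0.2, 0.14, 0.1, 0.1, 0.05),
                                 seed = 1), "strictly decrease")
  expect_error(evolve_references(per_rank_fanout = c(0, 1, 1, 1, 1)), "fanout")
})

test_that("congeneric species sit at the species-level divergence", {
  # two species in one genus at 2% target divergence; count the substitutions
  # the generator actually placed (binomial sampling tolerance)
  db <- evolve_references(n_phyla = 1, per_rank_fanout = c(1, 1, 1, 1, 2),
                          divergence_per_rank = c(0.30, 0.20, 0.14, 0.10, 0.06, 0.02),
                          seed = 8)
  expect_length(db, 2L)
  s <- strsplit(unname(db$seqs), "", fixed = TRUE)
  mism <- sum(s[[1]] != s[[2]])
  L <- nchar(db$seqs[[1]])
  # expected ~ L * 0.02 substitutions (slightly fewer: protected primer sites,
  # coincident hits); 4 sd binomial window around the target
  expect_gt(mism, L * 0.02 - 4 * sqrt(L * 0.02))
  expect_lt(mism, L * 0.02 + 4 * sqrt(L * 0.02))
  # alignment identity ~ 98%
  expect_equal(shearcoi:::global_identity(db$seqs[[1]], db$seqs[[2]]), 0.98,
               tolerance = 0.01)
})

test_that("pairwise divergence grows the shallower the split rank", {
  db <- fx_refdb16()
  lm <- shearcoi:::lineage_matrix(db$taxonomy)
  div <- function(a, b) {
    sa <- strsplit(db$seqs[[a]], "", fixed = TRUE)[[1]]
    sb <- strsplit(db$seqs[[b]], "", fixed = TRUE)[[1]]
    mean(sa != sb)
  }
  # ref001/ref002: same family, different genus; ref001/ref003: different
  # order; ref001/ref005: different class; ref001/ref009: different phylum
  expect_lt(div("ref001", "ref002"), div("ref001", "ref003"))
  expect_lt(div("ref001", "ref003"), div("ref001", "ref005"))
  expect_lt(div("ref001", "ref005"), div("ref001", "ref009"))
})

test_that("in-silico PCR finds the primer-to-primer product on both strands", {
  p <- folmer_primers()
  insert <- withr::with_seed(21, shearcoi:::random_dna(658))
  pad <- withr::with_seed(22, shearcoi:::random_dna(60, 2))
  template <- paste0(pad[1], p$forward, insert, revcomp(p$reverse), pad[2])
  amps <- in_silico_pcr(template, p)
  expect_length(amps, 1L)
  expect_identical(nchar(amps), nchar(p$forward) + 658L + nchar(p$reverse))
  expect_identical(amps, paste0(p$forward, insert, revcomp(p$reverse)))

  # product on the minus strand is reported in plus orientation
  amps_rc <- in_silico_pcr(revcomp(template), p)
  expect_identical(amps_rc, amps)

  # no primer site -> empty
  none <- withr::with_seed(23, shearcoi:::random_dna(900))
  expect_length(in_silico_pcr(none, p), 0L)
})

test_that("primer binding tolerates mismatches outside the 3' clamp only", {
  p <- folmer_primers()
  insert <- withr::with_seed(31, shearcoi:::random_dna(658))
  site <- strsplit(p$forward, "", fixed = TRUE)[[1]]
  flip <- function(ch) setdiff(c("A", "C", "G", "T"), ch)[1]
  site[3] <- flip(site[3]); site[10] <- flip(site[10])
  template <- paste0(paste(site, collapse = ""), insert, revcomp(p$reverse))
  expect_length(in_silico_pcr(template, p), 1L)

  site[length(site)] <- flip(site[length(site)])  # clamp violation
  template <- paste0(paste(site, collapse = ""), insert, revcomp(p$reverse))
  expect_length(in_silico_pcr(template, p), 0L)
})

test_that("shearing draws uniform fragments proportional to weights", {
  amp <- fx_amplicon()
  frags <- shear_fragments(c(a = amp), c(250, 300), 2000, seed = 9)
  expect_identical(nrow(frags), 2000L)
  lens <- frags$end - frags$start + 1L
  expect_true(all(lens >= 250 & lens <= 300))
  expect_true(all(frags$seq == substring(amp, frags$start, frags$end)))
  # start positions uniform over the valid range given each fragment's
  # length: the probability integral transform must be uniform on [0, 1)
  u <- (frags$start - 1) / (nchar(amp) - lens + 1)
  bins <- cut(u, breaks = seq(0, 1, length.out = 11), include.lowest = TRUE)
  expect_gt(suppressWarnings(chisq.test(table(bins))$p.value), 1e-4)

  expect_identical(nrow(shear_fragments(c(a = amp), c(250, 300), 0, seed = 1)), 0L)

  # abundance-weighted source counts within binomial 3 sigma
  two <- c(x = amp, y = fx_mutate(amp, 0.2, 4))
  fr <- shear_fragments(two, c(250, 300), 10000, seed = 10,
                        weights = c(x = 0.9, y = 0.1))
  nx <- sum(fr$amp_id == "x")
  expect_lt(abs(nx - 9000), 3 * sqrt(10000 * 0.9 * 0.1))

  # amplicon shorter than the minimum fragment -> whole-length, flagged
  short <- substring(amp, 1, 180)
  fr2 <- shear_fragments(c(s = short), c(250, 300), 50, seed = 2)
  expect_true(all(fr2$whole))
  expect_true(all(fr2$end - fr2$start + 1L == 180L))
})

test_that("read simulation produces exact substrings at error rate zero", {
  amp <- fx_amplicon()
  frags <- shear_fragments(c(a = amp), c(250, 300), 200, seed = 12)
  pairs <- sequence_reads(frags, read_len = 150, sub_error_rate = 0, seed = 13)
  expect_identical(nrow(pairs), 200L)
  expect_true(all(pairs$seq1 == substring(frags$seq, 1, 150)))
  flen <- nchar(frags$seq)
  expect_true(all(pairs$seq2 == revcomp(substring(frags$seq, flen - 149L, flen))))
  expect_true(all(nchar(pairs$qual1) == nchar(pairs$seq1)))
  # truth table partitions reads over the amplicons
  expect_true(all(pairs$src_id == "a"))

  # 300 bp fragment: mates tile [1,150] and [151,300]
  f300 <- data.frame(amp_id = "a", start = 1L, end = 300L,
                     seq = substring(amp, 1, 300), whole = FALSE)
  pr <- sequence_reads(f300, 150, 0, seed = 1)
  expect_identical(pr$seq1, substring(amp, 1, 150))
  expect_identical(pr$seq2, revcomp(substring(amp, 151, 300)))
})

test_that("substitution errors occur at the configured rate", {
  amp <- fx_amplicon()
  frags <- shear_fragments(c(a = amp), c(250, 300), 400, seed = 14)
  pairs <- sequence_reads(frags, read_len = 150, sub_error_rate = 0.01, seed = 15)
  truth1 <- substring(frags$seq, 1, 150)
  flen <- nchar(frags$seq)
  truth2 <- revcomp(substring(frags$seq, flen - 149L, flen))
  count_mism <- function(a, b) {
    sum(mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
               a, b))
  }
  n_bases <- sum(nchar(pairs$seq1)) + sum(nchar(pairs$seq2))
  mism <- count_mism(pairs$seq1, truth1) + count_mism(pairs$seq2, truth2)
  expect_lt(abs(mism - n_bases * 0.01), 3 * sqrt(n_bases * 0.01 * 0.99))
  # qualities encode the error rate used: Q20 = '5'
  expect_identical(substring(pairs$qual1[1], 1, 1), "5")
})

test_that("a full simulation is byte-deterministic given the seed", {
  db <- fx_refdb10()
  cfg <- pipeline_config()
  sim1 <- simulate_community(db, cfg, coverage = 5, sub_error_rate = 0.005, seed = 33)
  sim2 <- simulate_community(db, cfg, coverage = 5, sub_error_rate = 0.005, seed = 33)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_community(sim1, d1); p2 <- write_community(sim2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
  # every read's truth points at exactly one amplified reference
  expect_true(all(sim1$pairs$src_id %in% names(sim1$amplicons)))
})
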