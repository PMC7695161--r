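# Length filtering, dereplication, chimera screening, clustering, consensus.

test_that("length filter keeps <= 712 and removes strictly longer contigs", {
  contigs <- data.frame(id = c("a", "b", "c"), seq = "N",
                        length = c(710L, 712L, 713L), mean_coverage = 1)
  lf <- length_filter(contigs, 712)
  expect_identical(lf$kept$length, c(710L, 712L))
  expect_identical(lf$removed$length, 713L)
  expect_identical(nrow(lf$kept) + nrow(lf$removed), nrow(contigs))

  all_in <- length_filter(contigs[1:2, ], 712)
  expect_identical(nrow(all_in$removed), 0L)
  empty <- length_filter(contigs[0, ], 712)
  expect_identical(nrow(empty$kept), 0L)
})

test_that("dereplication collapses replicates and canonical orientations", {
  a <- withr::with_seed(7, shearcoi:::random_dna(300))
  b <- withr::with_seed(8, shearcoi:::random_dna(300))
  f <- dereplicate(c(a, a, b))
  expect_identical(f$size, c(2L, 1L))
  expect_identical(f$seq[1], canonical_orientation(a))

  # a sequence and its reverse complement are the same feature
  f2 <- dereplicate(c(a, revcomp(a)))
  expect_identical(nrow(f2), 1L)
  expect_identical(f2$size, 2L)

  # distinct strings stay distinct, count preserved
  many <- withr::with_seed(9, shearcoi:::random_dna(120, 50))
  f3 <- dereplicate(many)
  expect_identical(nrow(f3), 50L)
  expect_true(all(f3$size == 1L))
  expect_identical(sum(f3$size), 50L)
})

test_that("greedy clustering matches a brute-force oracle replay", {
  # substitution-only features of equal length: true identity is
  # 1 - hamming/L, so the oracle needs no aligner
  base <- withr::with_seed(11, shearcoi:::random_dna(400))
  feats <- withr::with_seed(12, {
    n <- 30L
    seqs <- vapply(seq_len(n), function(i) {
      k <- sample(0:30, 1)
      chars <- strsplit(base, "", fixed = TRUE)[[1]]
      pos <- sample(400, k)
      for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      paste(chars, collapse = "")
    }, character(1))
    data.frame(seq = seqs, size = sample(1:20, n, replace = TRUE))
  })
  feats <- feats[!duplicated(feats$seq), ]

  oracle <- function(features, identity) {
    features <- features[order(-features$size, features$seq), ]
    cents <- character(); memb <- integer(nrow(features))
    ham_id <- function(x, y) {
      1 - sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]) / nchar(x)
    }
    for (i in seq_len(nrow(features))) {
      placed <- FALSE
      for (ci in seq_along(cents)) {
        if (ham_id(features$seq[i], cents[ci]) >= identity) {
          memb[i] <- ci; placed <- TRUE; break
        }
      }
      if (!placed) { cents <- c(cents, features$seq[i]); memb[i] <- length(cents) }
    }
    list(centroids = cents, membership = split(features$seq, memb))
  }

  for (idy in c(0.98, 0.95)) {
    got <- cluster_greedy(feats, identity = idy)
    want <- oracle(feats, idy)
    expect_identical(length(got), length(want$centroids))
    expect_identical(vapply(got, `[[`, character(1), "centroid"), want$centroids)
    for (ci in seq_along(got)) {
      expect_setequal(got[[ci]]$members$seq, want$membership[[ci]])
    }
  }
  # conservation of feature sizes across clusters
  cl <- cluster_greedy(feats, identity = 0.98)
  expect_identical(sum(vapply(cl, `[[`, integer(1), "total_size")),
                   sum(feats$size))
})

test_that("the 98% boundary separates 1% from 3% divergence at 700 bp", {
  base <- withr::with_seed(13, shearcoi:::random_dna(700))
  near <- fx_mutate_every(base, 100, seed = 14)   # 7 substitutions -> 99%
  far <- fx_mutate_every(base, 33, seed = 15)     # 21 substitutions -> 97%
  f_near <- data.frame(seq = canonical_orientation(c(base, near)), size = c(5L, 1L))
  f_far <- data.frame(seq = canonical_orientation(c(base, far)), size = c(5L, 1L))
  expect_length(cluster_greedy(f_near, 0.98), 1L)
  expect_length(cluster_greedy(f_far, 0.98), 2L)
})

test_that("members join the first (largest) matching centroid", {
  x <- withr::with_seed(16, shearcoi:::random_dna(500))
  y <- fx_mutate_every(x, 100, seed = 17)  # 5 subs, 99%
  z <- fx_mutate_every(x, 125, seed = 18)  # 4 subs, 99.2%
  feats <- data.frame(seq = canonical_orientation(c(x, y, z)), size = c(5L, 3L, 1L))
  cl <- cluster_greedy(feats, 0.98)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$centroid, canonical_orientation(x))
  expect_identical(cl[[1]]$total_size, 9L)

  # clustering at identity 1.0 equals dereplication
  expect_length(cluster_greedy(feats, 1.0), 3L)
  # at a very low threshold everything merges
  expect_length(cluster_greedy(feats, 0.05), 1L)
})

test_that("consensus takes the size-weighted majority, ties to the centroid", {
  cen <- strrep("A", 60)
  g_at_5 <- paste0(substring(cen, 1, 4), "G", substring(cen, 6, 60))
  cl <- list(centroid = cen,
             members = data.frame(seq = c(cen, g_at_5), size = c(3L, 1L)))
  expect_identical(cluster_consensus(cl), cen)

  # equal sizes: centroid base retained
  cl_tie <- list(centroid = cen,
                 members = data.frame(seq = c(cen, g_at_5), size = c(1L, 1L)))
  expect_identical(cluster_consensus(cl_tie), cen)

  # strict majority against the centroid wins
  cl_maj <- list(centroid = cen,
                 members = data.frame(seq = c(cen, g_at_5, g_at_5),
                                      size = c(1L, 2L, 2L)))
  expect_identical(cluster_consensus(cl_maj), g_at_5)

  # singleton cluster: consensus is the member
  single <- list(centroid = cen, members = data.frame(seq = cen, size = 1L))
  expect_identical(cluster_consensus(single), cen)
})

test_that("reference-based chimera screen flags cross-class splices only", {
  db <- fx_refdb16()
  cfg <- pipeline_config()
  s1 <- db$seqs[["ref001"]]  # phylum P01
  s9 <- db$seqs[["ref009"]]  # phylum P02
  splice <- paste0(substring(s1, 101, 400), substring(s9, 401, 700))
  pure <- substring(s1, 101, 700)
  rand <- withr::with_seed(19, shearcoi:::random_dna(600))
  feats <- data.frame(seq = canonical_orientation(c(splice, pure, rand)),
                      size = c(1L, 1L, 1L))
  res <- flag_chimeras(feats, db, config = cfg)
  expect_identical(nrow(res$flagged), 1L)
  expect_identical(res$flagged$seq, canonical_orientation(splice))
  # the no-hit random feature is kept (insufficient evidence)
  expect_true(canonical_orientation(rand) %in% res$clean$seq)
  expect_true(canonical_orientation(pure) %in% res$clean$seq)
})
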