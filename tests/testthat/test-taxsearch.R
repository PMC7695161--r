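# Seeded local-alignment search, e-values, LCA assignment, mode comparison.

test_that("e-values follow the Karlin-Altschul formula", {
  sch <- scoring_scheme(lambda = 1.0, K = 0.5)
  expect_equal(alignment_evalue(20, 100, 1000, sch), 0.5 * 1e5 * exp(-20))
  # monotone decreasing in score
  ev <- vapply(seq(10, 100, by = 10), alignment_evalue, numeric(1),
               query_len = 100, db_len = 1000, scheme = sch)
  expect_true(all(diff(ev) < 0))
  # linear in database length
  expect_equal(alignment_evalue(20, 100, 2000, sch),
               2 * alignment_evalue(20, 100, 1000, sch))
  expect_error(alignment_evalue(20, 0, 1000, sch), "positive")
  expect_error(scoring_scheme(match = -1), "match")
  expect_error(scoring_scheme(seed_len = 4), "seed_len")
})

test_that("a verbatim reference is its own best hit at identity 1", {
  db <- fx_refdb16()
  cfg <- pipeline_config()
  for (mode in c("sensitive", "high-identity")) {
    h <- search_refdb(db$seqs[["ref005"]], db, mode = mode, config = cfg)
    expect_identical(h$subject_id[1], "ref005")
    expect_equal(h$percent_identity[1], 1.0)
    expect_lte(nrow(h), cfg$top_hits)
    expect_true(all(h$evalue <= cfg$max_evalue))
    expect_true(all(h$percent_identity >= cfg$min_hit_identity))
  }
  # a reverse-complemented query maps identically
  h_rc <- search_refdb(revcomp(db$seqs[["ref005"]]), db, mode = "sensitive",
                       config = cfg)
  expect_identical(h_rc$subject_id[1], "ref005")
  expect_error(search_refdb("", db, config = cfg), "empty query")
})

test_that("random queries find nothing", {
  db <- fx_refdb16()
  q <- withr::with_seed(23, shearcoi:::random_dna(700))
  h <- search_refdb(q, db, mode = "sensitive", config = pipeline_config())
  expect_identical(nrow(h), 0L)
})

test_that("seed length separates the two sensitivity modes", {
  db <- fx_refdb16()
  cfg <- pipeline_config()
  # single-reference database; query mutated every 20 bp so no exact run
  # reaches the 28 bp high-identity seed, while 11 bp seeds abound
  solo <- ref_db(db$seqs["ref001"], db$taxonomy["ref001"])
  q <- fx_mutate_every(db$seqs[["ref001"]], 20, seed = 24)
  h_sens <- search_refdb(q, solo, mode = "sensitive", config = cfg)
  expect_identical(h_sens$subject_id[1], "ref001")
  expect_gt(h_sens$percent_identity[1], 0.9)
  h_high <- search_refdb(q, solo, mode = "high-identity", config = cfg)
  expect_identical(nrow(h_high), 0L)
})

test_that("results are invariant to database input order", {
  db <- fx_refdb16()
  cfg <- pipeline_config()
  perm <- withr::with_seed(25, sample(names(db$seqs)))
  db_perm <- ref_db(db$seqs[perm], db$taxonomy[perm])
  q <- fx_mutate(db$seqs[["ref003"]], 0.02, seed = 26)
  h1 <- search_refdb(q, db, mode = "sensitive", config = cfg)
  h2 <- search_refdb(q, db_perm, mode = "sensitive", config = cfg)
  expect_identical(h1, h2)
})

test_that("LCA truncates at the deepest unanimous rank", {
  tax <- fx_insect_taxonomy()
  a <- lca_assign(fake_hits(rep("aedes_aegypti", 4)), tax)
  expect_identical(a$assigned_rank, "species")
  expect_identical(unclass(a$lineage)[["species"]], "Aedes aegypti")

  a2 <- lca_assign(fake_hits(c("aedes_aegypti", "aedes_albopictus")), tax)
  expect_identical(a2$assigned_rank, "genus")
  expect_identical(unclass(a2$lineage)[["genus"]], "Aedes")

  a3 <- lca_assign(fake_hits(c("aedes_aegypti", "danio")), tax)
  expect_identical(a3$assigned_rank, "unknown-eukaryotic")
  expect_length(a3$lineage, 0L)

  a4 <- lca_assign(fake_hits(character(0))[0, ], tax)
  expect_identical(a4$assigned_rank, "unknown")
  expect_identical(a4$supporting_hits, 0L)

  expect_error(lca_assign(fake_hits("nosuch"), tax), "no lineage")
})

test_that("LCA matches a rank-wise intersection oracle on random hit sets", {
  tax <- fx_insect_taxonomy()
  ids <- names(tax)
  oracle <- function(subjects) {
    lins <- lapply(unique(subjects), function(s) unclass(tax[[s]]))
    out <- character(0)
    for (r in tax_ranks()) {
      vals <- vapply(lins, function(l) l[[r]], character(1))
      if (length(unique(vals)) == 1L) out <- c(out, vals[1]) else break
    }
    out
  }
  withr::with_seed(27, {
    for (i in 1:50) {
      subj <- sample(ids, sample(1:4, 1), replace = TRUE)
      got <- lca_assign(fake_hits(subj), tax)
      want <- oracle(subj)
      if (length(want) == 0L) {
        expect_identical(got$assigned_rank, "unknown-eukaryotic")
      } else {
        expect_identical(unname(unclass(got$lineage)), unname(want))
      }
    }
  })
})

test_that("near-verbatim queries recover genus or deeper in a dense db", {
  db <- fx_refdb_dense()  # 4 congeneric species per genus
  cfg <- pipeline_config()
  queries <- withr::with_seed(28, {
    src <- sample(names(db$seqs), 20, replace = TRUE)
    setNames(vapply(src, function(id) shearcoi:::mutate_seq(db$seqs[[id]], 0.01),
                    character(1)), sprintf("q%02d", 1:20))
  })
  res <- assign_queries(queries, db, mode = "sensitive", config = cfg)
  depth <- vapply(res$assignments, function(a)
    shearcoi:::rank_index(if (a$assigned_rank %in% c("unknown", "unknown-eukaryotic"))
      NA_character_ else a$assigned_rank), integer(1))
  expect_gte(mean(depth >= 5), 0.95)
})

test_that("mode comparison reports species-set asymmetry", {
  mk <- function(species) {
    lapply(species, function(s) {
      structure(list(query_id = s,
                     lineage = taxon_path("Arthropoda", "Insecta", "Diptera",
                                          "Culicidae", "Aedes", s),
                     assigned_rank = "species", supporting_hits = 4L),
                class = "lca_assignment")
    })
  }
  same <- compare_modes(mk(c("s1", "s2")), mk(c("s1", "s2")))
  expect_equal(same$frac_a_not_b, 0)
  expect_equal(same$frac_b_not_a, 0)

  cr <- compare_modes(mk(c("s1", "s2")), mk(c("s2", "s3")))
  expect_equal(cr$frac_a_not_b, 0.5)
  expect_equal(cr$frac_b_not_a, 0.5)
  expect_identical(cr$n_intersection, 1L)

  none <- compare_modes(mk(character(0)), mk("s1"))
  expect_true(is.na(none$frac_a_not_b))
})
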