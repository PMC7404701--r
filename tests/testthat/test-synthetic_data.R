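test_that("the generator is deterministic and keeps the G-X-Y frame", {
  spec <- synthetic_spec(n_triplets = 3, composition = c(P = 1), seed = 7)
  expect_equal(generate_collagen_like(spec)$sequence, "GPPGPPGPP")
  spec2 <- synthetic_spec(n_triplets = 50, seed = 99)
  a <- generate_collagen_like(spec2)
  b <- generate_collagen_like(spec2)
  expect_identical(a$sequence, b$sequence)
  chars <- strsplit(a$sequence, "")[[1]]
  expect_true(all(chars[seq(1, length(chars), 3)] == "G"))
  expect_error(synthetic_spec(n_triplets = 0, seed = 1), "n_triplets")
  expect_error(synthetic_spec(seed = 1, composition = c(P = 0)),
               "positive sum")
  expect_error(synthetic_spec(n_triplets = 3, composition = c(P = 1)),
               "seed")
})

test_that("planted motifs are recovered at their recorded positions", {
  spec <- synthetic_spec(
    n_triplets = 60,
    motifs = list(list(peptide = "RL", activity_code = "ah", copies = 3)),
    flank_mode = "cuttable", enzyme_sets = list("pepsin"), seed = 101)
  truth <- plant_motifs(generate_collagen_like(spec), spec)
  pos <- truth$planted_positions[["RL"]]
  expect_length(pos, 3L)
  for (s in pos) {
    expect_equal(substr(truth$protein$sequence, s + 1, s + 2), "RL")
  }
  # no accidental occurrences: count equals copies
  expect_equal(count_occurrences(truth$protein$sequence, "RL"), 3L)
  # frame preserved outside motifs
  chars <- strsplit(truth$protein$sequence, "")[[1]]
  motif_idx <- unlist(lapply(pos, function(s) (s + 1):(s + 2)))
  gly_idx <- setdiff(seq(1, length(chars), 3), motif_idx)
  expect_true(all(chars[gly_idx] == "G"))
})

test_that("cuttable flanks release every copy (W = 1) and inert flanks none", {
  spec <- synthetic_spec(
    n_triplets = 80,
    motifs = list(list(peptide = "RL", activity_code = "ah", copies = 3)),
    flank_mode = "cuttable", enzyme_sets = list("pepsin"), seed = 202)
  truth <- plant_motifs(generate_collagen_like(spec), spec)
  n <- truth$protein$n_residues
  expect_equal(unname(truth$expected_A[["ah"]]), 3 / n)
  expect_equal(unname(truth$expected_AE$pepsin[["ah"]]), 3 / n)
  expect_equal(unname(truth$expected_W$pepsin[["ah"]]), 1)

  # PGL planted with inert flanks is never released by trypsin
  spec2 <- synthetic_spec(
    n_triplets = 80, composition = c(P = 0.8, Q = 0.2),
    motifs = list(list(peptide = "PGL", activity_code = "ah", copies = 2)),
    flank_mode = "inert", enzyme_sets = list("trypsin"), seed = 203)
  truth2 <- plant_motifs(generate_collagen_like(spec2), spec2)
  expect_equal(unname(truth2$expected_A[["ah"]]),
               2 / truth2$protein$n_residues)
  expect_equal(unname(truth2$expected_AE$trypsin[["ah"]]), 0)
})

test_that("ground truth without motifs still carries DH_t", {
  spec <- synthetic_spec(n_triplets = 40, motifs = list(),
                         enzyme_sets = list("pepsin", "trypsin"), seed = 11)
  truth <- plant_motifs(generate_collagen_like(spec), spec)
  expect_length(truth$expected_A, 0L)
  expect_true(all(c("pepsin", "trypsin") %in% names(truth$expected_DHt)))
  expect_true(all(truth$expected_DHt >= 0 & truth$expected_DHt <= 100))
})

test_that("the synthetic database mirrors the motif list", {
  spec <- synthetic_spec(
    n_triplets = 30,
    motifs = list(list(peptide = "RL", activity_code = "ah", copies = 1),
                  list(peptide = "RL", activity_code = "dpp", copies = 1)),
    seed = 5)
  db <- make_synthetic_db(spec)
  expect_equal(nrow(db$records), 2L)
  expect_equal(unique(db$records$peptide), "RL")
  empty <- make_synthetic_db(synthetic_spec(n_triplets = 3, seed = 5))
  expect_equal(nrow(empty$records), 0L)
})

test_that("pipeline outputs equal the brute-force expectations exactly", {
  set.seed(51)
  rs <- default_ruleset()
  for (i in 1:12) {
    spec <- synthetic_spec(
      n_triplets = sample(40:90, 1),
      motifs = list(
        list(peptide = "RL", activity_code = "ah", copies = sample(1:3, 1)),
        list(peptide = "GF", activity_code = "dpp", copies = sample(1:2, 1))),
      flank_mode = sample(c("cuttable", "inert"), 1),
      enzyme_sets = list("pepsin", "trypsin", c("pepsin", "trypsin")),
      seed = 1000 + i)
    truth <- plant_motifs(generate_collagen_like(spec), spec)
    p <- truth$protein
    db <- truth$db
    occ <- profile_occurrence(p, db, include_zero = TRUE)
    for (code in names(truth$expected_A)) {
      expect_identical(occ$A[occ$activity_code == code],
                       unname(truth$expected_A[[code]]))
    }
    for (set_label in names(truth$expected_DHt)) {
      enz <- resolve_enzymes(strsplit(set_label, "+", fixed = TRUE)[[1]], rs)
      dg <- digest(p, enz)
      expect_identical(dg$dh_t, unname(truth$expected_DHt[[set_label]]))
      rel <- profile_release(p, dg, db, occurrence = occ,
                             include_zero = TRUE)
      for (code in names(truth$expected_AE[[set_label]])) {
        expect_identical(rel$A_E[rel$activity_code == code],
                         unname(truth$expected_AE[[set_label]][[code]]))
      }
    }
  }
})

test_that("synthetic fixtures round-trip through FASTA/TSV/JSON", {
  spec <- synthetic_spec(
    n_triplets = 30,
    motifs = list(list(peptide = "RL", activity_code = "ah", copies = 2)),
    seed = 77)
  truth <- plant_motifs(generate_collagen_like(spec), spec)
  dir <- tempfile()
  paths <- write_synthetic_fixture(truth, dir)
  back <- read_fasta(paths[1])[[1]]
  expect_equal(back$sequence, truth$protein$sequence)
  db <- load_activity_table(paths[2])
  expect_equal(db$records$peptide, truth$db$records$peptide)
  js <- jsonlite::read_json(paths[3])
  expect_equal(js$protein_id, truth$protein$id)
})
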