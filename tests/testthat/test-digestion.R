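rs <- default_ruleset()

test_that("ruleset parsing validates schema and residue sets", {
  expect_setequal(names(rs), c("stem_bromelain", "ficin", "papain",
                               "pepsin", "trypsin", "chymotrypsin"))
  tr <- rs$trypsin
  expect_length(tr$rules, 1L)
  expect_setequal(tr$rules[[1]]$window$P1$residues, c("K", "R"))
  expect_equal(tr$rules[[1]]$window[["P1'"]]$type, "deny")

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("enzymes:", "  bad:", "    rules:",
               "      - P2: {allow: F}"), yml)
  expect_error(parse_ruleset(yml), "must constrain P1")
  writeLines(c("enzymes:", "  bad:", "    rules:",
               "      - P1: {allow: KZ}"), yml)
  expect_error(parse_ruleset(yml), "non-standard")
  writeLines(c("enzymes:", "  bad:", "    rules: []"), yml)
  expect_error(parse_ruleset(yml), "empty rule list")
  expect_error(cleavage_rule(P1 = allow("")), "empty residue set")
})

test_that("cut sites match hand-enumerated examples", {
  toy <- protein_record("toy", "GKGFRL")
  expect_equal(find_cut_sites(toy, rs["trypsin"]), c(1L, 4L))
  expect_equal(find_cut_sites(protein_record("t", "GKGFRPL"), rs["trypsin"]),
               1L)  # proline suppresses the Arg site
  expect_equal(find_cut_sites(toy, rs["pepsin"]), 3L)
  expect_equal(find_cut_sites(toy, rs[c("pepsin", "trypsin")]),
               c(1L, 3L, 4L))  # terminal Leu has no following bond
})

test_that("digest fragments partition the chain and DH_t follows its definition", {
  toy <- protein_record("toy", "GKGFRL")
  d <- digest(toy, rs["trypsin"])
  expect_equal(d$fragments$sequence, c("GK", "GFR", "L"))
  expect_equal(d$dh_t, 40)
  expect_equal(nrow(d$fragments), length(d$cut_sites) + 1L)
  expect_equal(paste(d$fragments$sequence, collapse = ""), toy$sequence)

  d2 <- digest(toy, rs["pepsin"])
  expect_equal(d2$fragments$sequence, c("GKGF", "RL"))
  expect_equal(d2$dh_t, 20)

  d0 <- digest(protein_record("inert", "AAAA"), rs["trypsin"])
  expect_equal(d0$fragments$sequence, "AAAA")
  expect_equal(theoretical_degree_of_hydrolysis(d0), 0)

  d3 <- digest(toy, rs[c("pepsin", "trypsin")])
  expect_equal(theoretical_degree_of_hydrolysis(d3), 60)

  d1 <- digest(protein_record("single", "G"), rs["trypsin"])
  expect_equal(d1$dh_t, 0)
  expect_equal(nrow(d1$fragments), 1L)
})

test_that("window constraints fail allow / satisfy deny off the termini", {
  # P2' allow: satisfied in-sequence, failed when P2' is off the end
  e <- enzyme_spec("probe", rules = cleavage_rule(P1 = allow("A"),
                                                  `P2'` = allow("G")))
  expect_equal(find_cut_sites(protein_record("p", "AAGG"), e), c(0L, 1L))
  expect_equal(find_cut_sites(protein_record("p", "GAA"), e), integer(0))
  # P4 deny is satisfied when P4 is off-sequence
  e2 <- enzyme_spec("probe2", rules = cleavage_rule(P1 = allow("A"),
                                                    P4 = deny("G")))
  expect_equal(find_cut_sites(protein_record("p", "GAAA"), e2), c(1L, 2L))
})

test_that("engine agrees with the brute-force oracle on random sequences", {
  set.seed(41)
  sets <- c(lapply(names(rs), function(n) rs[n]),
            list(rs[c("pepsin", "trypsin")],
                 rs[c("pepsin", "trypsin", "chymotrypsin")]))
  for (i in 1:120) {
    s <- random_sequence(sample(2:50, 1))
    p <- protein_record("r", s)
    for (enz in sets) {
      expect_identical(find_cut_sites(p, enz),
                       as.integer(oracle_cut_sites(s, enz)))
    }
  }
})

test_that("digest reports list fragments with coordinates and DH_t", {
  d <- digest(protein_record("toy", "GKGFRL"), rs["trypsin"])
  path <- tempfile(fileext = ".tsv")
  write_digest_report(d, path)
  lines <- readLines(path)
  expect_equal(lines[1], "protein_id\tstart\tend\tsequence")
  expect_equal(lines[2], "toy\t0\t2\tGK")
  expect_match(lines[length(lines)], "DH_t=40.00", fixed = TRUE)
})

test_that("cut sets are order-invariant and additive across enzymes", {
  set.seed(42)
  pt <- rs[c("pepsin", "trypsin")]
  tp <- rs[c("trypsin", "pepsin")]
  for (i in 1:60) {
    p <- protein_record("r", random_sequence(sample(2:60, 1)))
    expect_identical(digest(p, pt)$cut_sites, digest(p, tp)$cut_sites)
    a <- find_cut_sites(p, rs["pepsin"])
    b <- find_cut_sites(p, rs["trypsin"])
    ab <- find_cut_sites(p, pt)
    expect_identical(ab, sort(union(a, b)))
    dh_a <- digest(p, rs["pepsin"])$dh_t
    dh_b <- digest(p, rs["trypsin"])$dh_t
    dh_ab <- digest(p, pt)$dh_t
    expect_gte(dh_ab, max(dh_a, dh_b))
    expect_lte(dh_ab, dh_a + dh_b + 1e-12)
    if (!length(intersect(a, b))) expect_equal(dh_ab, dh_a + dh_b)
  }
})
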