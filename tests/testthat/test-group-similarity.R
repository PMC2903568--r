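test_that("AVG and BMA combiners reduce score matrices correctly", {
  fx <- ic_fixture()
  # singleton groups: AVG = BMA = the single pair score
  s_mn <- term_pair_score("lin", fx$dag, fx$ic, "m", "n")$value
  expect_equal(combine_avg("lin", fx$dag, fx$ic, "m", "n"), s_mn)
  expect_equal(combine_bma("lin", fx$dag, fx$ic, "m", "n"), s_mn)
  # identical singleton: the identity score
  expect_equal(combine_avg("jiang", fx$dag, fx$ic, "m", "m"), 1)

  # {m, n} vs {a}: AVG = mean of the two pair scores
  s_ma <- term_pair_score("lin", fx$dag, fx$ic, "m", "a")$value
  s_na <- term_pair_score("lin", fx$dag, fx$ic, "n", "a")$value
  expect_equal(combine_avg("lin", fx$dag, fx$ic, c("m", "n"), "a"),
               (s_ma + s_na) / 2)

  # BMA on a printed 2x2 matrix: row maxes (0.9, 0.8), col maxes (0.9, 0.8)
  S <- matrix(c(0.9, 0.2, 0.1, 0.8), 2)
  expect_equal(gosimnorm:::bma_matrix(S), 0.85)
  expect_equal(gosimnorm:::bma_matrix(S, alternative = TRUE),
               (0.9 + 0.8 + 0.9 + 0.8) / 4)
  # identical groups under lin: every term best-matches itself
  expect_equal(combine_bma("lin", fx$dag, fx$ic, c("m", "n"), c("m", "n")), 1)
  expect_error(combine_avg("lin", fx$dag, fx$ic, character(), "a"), "empty")
})

test_that("overlap family follows the diamond fixture by hand", {
  dag <- diamond_dag()
  # closed({d}) = {d,b,c,r}; closed({b}) = {b,r}
  expect_equal(to_score(dag, "d", "b"), 2)
  expect_equal(overlap_score("nto", dag, "d", "b"), 2 / 2)
  expect_equal(overlap_score("dice", dag, "d", "b"), 2 * 2 / (4 + 2))
  # identical groups
  expect_equal(to_score(dag, "d", "d"), 4)
  expect_equal(overlap_score("nto", dag, "d", "d"), 1)
  expect_equal(overlap_score("dice", dag, "d", "d"), 1)
  # nested closures: NTO = 1
  expect_equal(overlap_score("nto", dag, "b", c("b", "d")), 1)
  # groups sharing only the root
  sib <- ontology_dag(c("r", "s", "t"), list(character(), "r", "r"))
  expect_equal(to_score(sib, "s", "t"), 1)
  # direct-length denominators behind the flag
  expect_equal(overlap_score("nto", dag, "d", "b", denominator = "direct"), 2)
})

test_that("kappa matches a hand-computed Cohen's kappa and its edge cases", {
  uni <- forged_universe(letters[1:10])
  g1 <- forged_group("a", c("a", "b", "c"))
  g2 <- forged_group("a", c("a", "b", "d"))
  # agree on 8/10 cells; E = 0.3*0.3 + 0.7*0.7 = 0.58
  expect_equal(kappa_score(uni, g1, g2), (0.8 - 0.58) / (1 - 0.58))
  # identical vectors
  expect_equal(kappa_score(uni, g1, g1), 1)
  # both vectors all ones: O = E = 1, defined as 1
  full <- forged_group("a", letters[1:10])
  expect_equal(kappa_score(uni, full, full), 1)
  # below-chance agreement clamps to zero
  h1 <- forged_group("a", letters[1:5])
  h2 <- forged_group("f", letters[6:10])
  expect_equal(kappa_score(uni, h1, h2), 0)
})

test_that("GIC and VSM weight overlaps by information content", {
  uni <- forged_universe(c("r", "b", "d"))
  ic <- forged_ic(c(r = 0, b = 1, d = 2))
  g1 <- forged_group("b", c("r", "b"))
  g2 <- forged_group("d", c("r", "b", "d"))
  expect_equal(weighted_set_score("gic", uni, ic, g1, g2), 1 / 3)
  expect_equal(weighted_set_score("vsm", uni, ic, g1, g2), 1 / sqrt(5))
  # identical sets with positive IC
  expect_equal(weighted_set_score("gic", uni, ic, g2, g2), 1)
  expect_equal(weighted_set_score("vsm", uni, ic, g2, g2), 1)
  # intersection carrying zero IC only
  root1 <- forged_group("r", "r")
  expect_equal(weighted_set_score("gic", uni, ic, root1, g2), 0)
  expect_equal(weighted_set_score("vsm", uni, ic, root1, root1), 0)
})

test_that("protein_similarity dispatches, records lengths and is symmetric", {
  sc <- small_scenario(21)
  genes <- names(sc$corpus$annotations)
  g1 <- genes[1]; g2 <- genes[2]
  self <- protein_similarity("jiang_bma", sc$dag, sc$ic, sc$corpus, g1, g1)
  expect_equal(self$value, 1)  # jiang(t, t) = 1 for every term
  L <- annotation_length(sc$corpus)[[g1]]
  expect_equal(self$lengths, c(L, L))
  expect_error(protein_similarity("lin_bma", sc$dag, sc$ic, sc$corpus,
                                  g1, "ghost"), "unknown gene")
  for (meas in c("rs_bma", "to", "kappa", "gic")) {
    ab <- protein_similarity(meas, sc$dag, sc$ic, sc$corpus, g1, g2)
    ba <- protein_similarity(meas, sc$dag, sc$ic, sc$corpus, g2, g1)
    expect_equal(ab$value, ba$value)
    expect_equal(ab$lengths, ba$lengths)
  }
})

test_that("all 14 measures agree with the naive oracle on random small cases", {
  for (seed in 1:3) {
    sc <- small_scenario(seed, n_terms = 20, n_genes = 40)
    pool <- sc$dag$terms[!is.na(sc$ic$ic)]
    set.seed(seed + 500)
    for (rep in 1:8) {
      t1 <- sample(pool, sample(1:3, 1))
      t2 <- sample(pool, sample(1:3, 1))
      batch <- score_pairs(sc$engine, list(t1), list(t2))[1, ]
      for (meas in group_measures) {
        naive <- naive_group_score(meas, sc$dag, sc$ic, t1, t2)
        expect_equal(batch[[meas]], naive, tolerance = 1e-12,
                     label = sprintf("%s (seed %d rep %d)", meas, seed, rep))
        single <- gosimnorm:::group_pair_score(
          meas, sc$dag, sc$ic,
          term_group(sc$dag, t1), term_group(sc$dag, t2))
        expect_equal(single, naive, tolerance = 1e-12)
      }
    }
  }
})

test_that("all 14 measures are symmetric and within Table-style ranges", {
  sc <- small_scenario(31, n_terms = 80, n_genes = 200)
  pool <- sc$dag$terms[!is.na(sc$ic$ic)]
  set.seed(77)
  gl1 <- replicate(150, sample(pool, sample(1:5, 1)), simplify = FALSE)
  gl2 <- replicate(150, sample(pool, sample(1:5, 1)), simplify = FALSE)
  fwd <- score_pairs(sc$engine, gl1, gl2)
  rev <- score_pairs(sc$engine, gl2, gl1)
  expect_equal(fwd, rev, tolerance = 1e-12)
  expect_true(all(fwd[, "to"] >= 1))             # single-root ontology
  for (meas in c("nto", "dice", "jiang_avg", "jiang_bma")) {
    expect_true(all(fwd[, meas] > 0 & fwd[, meas] <= 1))
  }
  for (meas in c("kappa", "gic", "vsm", "lin_avg", "lin_bma")) {
    expect_true(all(fwd[, meas] >= 0 & fwd[, meas] <= 1))
  }
  for (meas in c("rs_avg", "rs_bma", "resnik_avg", "resnik_bma")) {
    expect_true(all(fwd[, meas] >= 0))
  }
  expect_true(all(fwd[, "rs_avg"] <= fwd[, "lin_avg"]))
})

test_that("protein similarity matrix is symmetric with unit-like diagonal", {
  sc <- small_scenario(41, n_terms = 50, n_genes = 25)
  S <- protein_similarity_matrix(sc$engine, sc$corpus, "jiang_bma")
  expect_lt(max(abs(S - t(S))), 1e-15)
  expect_equal(unname(diag(S)), rep(1, nrow(S)))  # jiang(t, t) = 1
  g <- names(sc$corpus$annotations)[c(3, 9)]
  expect_equal(S[g[1], g[2]],
               protein_similarity("jiang_bma", sc$dag, sc$ic, sc$corpus,
                                  g[1], g[2])$value)
})
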