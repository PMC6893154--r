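test_that("divergence matrix counts site patterns with pairwise deletion", {
  D <- divergence_matrix("ACGT", "ACGT")
  expect_equal(unname(diag(D$counts)), rep(1L, 4))
  expect_equal(D$n_counted, 4L)

  D2 <- divergence_matrix("AAAA", "AACC")
  expect_equal(D2$counts["A", "A"], 2L, ignore_attr = TRUE)
  expect_equal(D2$counts["A", "C"], 2L, ignore_attr = TRUE)
  expect_equal(sum(D2$counts), 4L)

  D3 <- divergence_matrix("AC-T", "ACNT")
  expect_equal(D3$n_counted, 3L)
  expect_equal(D3$n_excluded, 1L)
  D4 <- divergence_matrix("AC-T", "ANNT")
  expect_equal(D4$n_counted, 2L)
  expect_equal(D4$n_excluded, 2L)

  expect_error(divergence_matrix("ACG", "ACGT"), "length mismatch")
})

test_that("divergence matrix depends on site patterns, not site order", {
  set.seed(42)
  s1 <- sample(nt, 60, replace = TRUE)
  s2 <- sample(nt, 60, replace = TRUE)
  perm <- sample(60)
  D <- divergence_matrix(s1, s2)
  Dp <- divergence_matrix(s1[perm], s2[perm])
  expect_identical(D$counts, Dp$counts)
  r <- matched_pairs_tests(D)
  rp <- matched_pairs_tests(Dp)
  expect_equal(r$MPTS$statistic, rp$MPTS$statistic)
  expect_equal(r$MPTMS$p_value, rp$MPTMS$p_value)
})

test_that("worked 4x4 matrix reproduces the independently derived values", {
  D <- as_divergence_matrix(worked_matrix())
  b <- bowker_test(D)
  s <- stuart_test(D)
  i <- internal_test(b, s, D)
  ob <- oracle_bowker(worked_matrix())
  os <- oracle_stuart(worked_matrix())
  expect_equal(b$statistic, ob$stat, tolerance = 1e-12)
  expect_equal(b$df, 6L)
  expect_equal(b$p_value, ob$p, tolerance = 1e-12)
  expect_equal(os$u, c(-6, 4, 5))
  expect_equal(s$statistic, os$stat, tolerance = 1e-12)
  expect_equal(s$df, 3L)
  expect_equal(i$statistic, ob$stat - os$stat, tolerance = 1e-12)
  expect_equal(i$df, 3L)
  # frozen values from the oracle
  expect_equal(b$statistic, 8.225108, tolerance = 1e-6)
  expect_equal(s$statistic, 2.547772, tolerance = 1e-6)
  expect_equal(i$statistic, 5.677336, tolerance = 1e-6)
})

test_that("a 2x2 off-diagonal matrix matches the hand-computed statistic", {
  d <- matrix(c(0, 5, 1, 0), 2, 2, byrow = TRUE)
  b <- bowker_test(as_divergence_matrix(d))
  expect_equal(b$statistic, (5 - 1)^2 / 6)
  expect_equal(b$df, 1L)
})

test_that("symmetric matrices give statistic 0 and p = 1", {
  d <- worked_matrix()
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  D <- as_divergence_matrix(d)
  r <- matched_pairs_tests(D)
  expect_equal(r$MPTS$statistic, 0)
  expect_equal(r$MPTS$p_value, 1)
  expect_equal(r$MPTMS$statistic, 0)
  expect_equal(r$MPTMS$p_value, 1)
  expect_equal(r$MPTIS$statistic, 0)
  expect_equal(r$MPTIS$p_value, 1)
})

test_that("degenerate matrices are marked inapplicable, not scored", {
  # identical sequences: no off-diagonal information
  D <- divergence_matrix("ACGTACGT", "ACGTACGT")
  b <- bowker_test(D)
  expect_false(b$applicable)
  expect_true(is.na(b$p_value))
  s <- stuart_test(D)   # V is the zero matrix
  expect_false(s$applicable)
  expect_match(s$note, "singular")
  i <- internal_test(b, s, D)
  expect_false(i$applicable)
})

test_that("for m = 2 Stuart equals Bowker and the internal test has df 0", {
  set.seed(7)
  for (rep in 1:20) {
    d <- matrix(rpois(4, 6), 2, 2)
    d[1, 2] <- d[1, 2] + 1  # ensure off-diagonal information
    D <- as_divergence_matrix(d)
    b <- bowker_test(D)
    s <- stuart_test(D)
    if (!s$applicable) next
    expect_equal(s$statistic, b$statistic, tolerance = 1e-12)
    i <- internal_test(b, s, D)
    expect_false(i$applicable)
    expect_equal(i$df, 0L)
  }
})

test_that("all p-values are invariant under transposing the matrix", {
  set.seed(11)
  for (rep in 1:25) {
    d <- random_divmat()
    r1 <- matched_pairs_tests(as_divergence_matrix(d))
    r2 <- matched_pairs_tests(as_divergence_matrix(t(d)))
    expect_equal(r1$MPTS$statistic, r2$MPTS$statistic, tolerance = 1e-12)
    for (t in c("MPTS", "MPTMS", "MPTIS")) {
      expect_equal(r1[[t]]$applicable, r2[[t]]$applicable)
      if (r1[[t]]$applicable) {
        expect_equal(r1[[t]]$p_value, r2[[t]]$p_value, tolerance = 1e-10)
      }
    }
  }
})

test_that("the decomposition S_B = S_S + S_I holds whenever all applicable", {
  set.seed(13)
  for (rep in 1:25) {
    d <- random_divmat()
    r <- matched_pairs_tests(as_divergence_matrix(d))
    if (all(vapply(r, `[[`, TRUE, "applicable"))) {
      expect_equal(r$MPTS$statistic,
                   r$MPTMS$statistic + r$MPTIS$statistic,
                   tolerance = 1e-10)
      expect_gte(r$MPTS$statistic, 0)
      expect_gte(r$MPTIS$statistic, 0)
    }
  }
})

test_that("results serialize to a tabular record", {
  tab <- test_results_table(
    matched_pairs_tests(as_divergence_matrix(worked_matrix())))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$test, c("MPTS", "MPTMS", "MPTIS"))
  expect_true(all(c("statistic", "df", "p_value", "applicable", "note")
                  %in% names(tab)))
})
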