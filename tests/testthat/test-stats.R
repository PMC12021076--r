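test_that("two-sample t matches the pooled-variance formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  res <- two_sample_t(a, b)
  oracle <- oracle_pooled_t(a, b)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  expect_equal(abs(res$statistic), 1.224745, tolerance = 1e-6)

  set.seed(3)
  x <- rnorm(12, 5, 2); y <- rnorm(9, 6, 2)
  res2 <- two_sample_t(x, y)
  o2 <- oracle_pooled_t(x, y)
  expect_equal(res2$statistic, o2$t, tolerance = 1e-6)
  expect_equal(res2$df, 19)
  expect_equal(res2$p_value, o2$p, tolerance = 1e-6)

  # identical groups: t = 0, p = 1; swapping flips the sign only
  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sw <- two_sample_t(b, a)
  expect_equal(sw$statistic, -res$statistic)
  expect_equal(sw$p_value, res$p_value)
  expect_error(two_sample_t(1, a), "at least 2")
})

test_that("one-sample t matches the formula and handles degeneracies", {
  v <- c(1.2, 1.4, 1.6)
  res <- one_sample_t(v, 1)
  oracle <- oracle_one_t(v, 1)
  expect_equal(res$statistic, oracle$t, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)

  # translation invariance: shifting values and reference together
  res_shift <- one_sample_t(v + 5, 6)
  expect_equal(res_shift$statistic, res$statistic, tolerance = 1e-9)

  flat <- one_sample_t(c(1, 1, 1), 1)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  degen <- one_sample_t(c(2, 2, 2), 1)
  expect_true(degen$infinite_statistic)
  expect_true(is.infinite(degen$statistic))
  expect_lte(degen$p_value, .Machine$double.xmin)
})

test_that("ANOVA + Tukey matches the F and studentized-range formulas", {
  set.seed(7)
  groups <- list(ctl = rnorm(8, 0), mid = rnorm(8, 1), high = rnorm(8, 2))
  res <- anova_tukey(groups)
  oracle <- oracle_anova(groups)
  expect_equal(res$statistic, oracle$f, tolerance = 1e-6)
  expect_equal(res$df, c(oracle$df1, oracle$df2))
  expect_equal(res$p_value, oracle$p, tolerance = 1e-6)
  expect_equal(sort(res$tukey$p_adj), sort(oracle$tukey[, "p_adj"]),
               tolerance = 1e-6)

  # three identical groups: F = 0, all adjusted p = 1
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res0 <- anova_tukey(g0)
  expect_equal(res0$statistic, 0)
  expect_true(all(res0$tukey$p_adj == 1))

  # permuting group order permutes but does not change the pairwise table
  perm <- anova_tukey(groups[c(3, 1, 2)])
  canon <- function(tab) {
    key <- vapply(strsplit(tab$pair, "-"), function(p)
      paste(sort(p), collapse = "|"), character(1))
    tab$p_adj[order(key)]
  }
  expect_equal(canon(perm$tukey), canon(res$tukey), tolerance = 1e-9)

  expect_error(anova_tukey(groups[1:2]), "two_sample_t")
})

test_that("empirical type-I error sits at the nominal 5 percent criterion", {
  n_rep <- 4000
  set.seed(11)
  p_two <- replicate(n_rep, two_sample_t(rnorm(6), rnorm(6))$p_value)
  expect_lt(abs(mean(p_two < 0.05) - 0.05), 0.01)
  p_one <- replicate(n_rep, one_sample_t(rnorm(6, 1), 1)$p_value)
  expect_lt(abs(mean(p_one < 0.05) - 0.05), 0.01)
})
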