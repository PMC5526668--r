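test_that("exact r x c Fisher matches the reference implementation", {
  # the rescue table from printed counts: p ~ 3e-5
  tab <- rbind(rescued = c(0, 10, 0, 8), extinct = c(95, 85, 95, 87))
  res <- fisher_exact_rxc(tab)
  expect_equal(res$method, "exact")
  expect_lte(res$n_tables, 1330)
  expect_equal(res$p_value, stats::fisher.test(tab)$p.value, tolerance = 1e-10)
  # identical columns -> p = 1
  expect_equal(fisher_exact_rxc(cbind(c(3, 7), c(3, 7)))$p_value, 1)
  # randomized cross-check against stats::fisher.test
  withr::local_seed(11)
  for (i in 1:15) {
    t2 <- matrix(rpois(6, 5), 2, 3)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact_rxc(t2)$p_value, stats::fisher.test(t2)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_rxc(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("2 x 2 case equals the hypergeometric closed form", {
  t2 <- matrix(c(1, 9, 9, 1), 2, 2)
  closed <- 2 * (choose(10, 1) * choose(10, 9) + 1) / choose(20, 10)
  expect_equal(fisher_exact_rxc(t2)$p_value, closed, tolerance = 1e-12)
  # general 2 x 2: sum of dhyper mass <= observed
  withr::local_seed(12)
  for (i in 1:15) {
    m <- matrix(rpois(4, 6), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    K <- sum(m[1, ]); n <- sum(m); k <- sum(m[, 1])
    x <- max(0, k - (n - K)):min(K, k)
    d <- dhyper(x, K, n - K, k)
    closed <- sum(d[d <= dhyper(m[1, 1], K, n - K, k) * (1 + 1e-7)])
    expect_equal(fisher_exact_rxc(m)$p_value, closed, tolerance = 1e-9)
  }
})

test_that("p-values are invariant under row/column permutation", {
  withr::local_seed(13)
  t2 <- matrix(rpois(8, 4) + 1, 2, 4)
  p <- fisher_exact_rxc(t2)$p_value
  expect_equal(fisher_exact_rxc(t2[2:1, ])$p_value, p, tolerance = 1e-12)
  expect_equal(fisher_exact_rxc(t2[, c(3, 1, 4, 2)])$p_value, p,
               tolerance = 1e-12)
})

test_that("Monte-Carlo Fisher fallback agrees with exact within 3 SE", {
  t2 <- rbind(c(4, 9, 2), c(8, 3, 7))
  ex <- fisher_exact_rxc(t2)$p_value
  mc <- fisher_exact_rxc(t2, budget = 5, mc_reps = 20000, seed = 7)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p_value - ex), 3 * mc$mc_se + 1e-4)
})

test_that("odds ratios reproduce the published cost-analysis values", {
  # rescue odds, IS-deletion strain vs reference: 5/12 vs 76/18
  expect_equal(round(odds_ratio_2x2(5, 12, 76, 18), 1), 0.1)
  # extinction odds, locus A vs reference (pooled replicates): 8/4 vs 58/168
  expect_equal(round(odds_ratio_2x2(8, 4, 58, 168), 1), 5.8)
  expect_equal(odds_ratio_2x2(3, 5, 3, 5), 1)
  # zero-cell markers, no continuity correction
  expect_equal(odds_ratio_2x2(0, 9, 5, 9), 0)
  expect_equal(odds_ratio_2x2(5, 0, 5, 9), Inf)
  expect_equal(odds_ratio_2x2(0, 5, 5, 0), 0)      # numerator zero
  expect_true(is.nan(odds_ratio_2x2(0, 5, 0, 5)))  # both products zero
  expect_equal(odds_ratio_2x2(5, 12, 76, 18, orientation = "reciprocal"),
               1 / odds_ratio_2x2(5, 12, 76, 18))
})

test_that("permutation test: exact enumeration and MC agreement", {
  res <- permutation_test_two_sample(c(1, 2), c(3, 4))
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 / 6)
  expect_equal(permutation_test_two_sample(rep(2, 3), rep(2, 4))$p_value, 1)
  # seeded MC agrees with exact enumeration within 3 MC SE (n = 8)
  withr::local_seed(14)
  x <- rnorm(4); y <- rnorm(4) + 1
  ex <- permutation_test_two_sample(x, y)$p_value
  mc <- permutation_test_two_sample(x, y, reps = 5000, seed = 3,
                                    exact_budget = 1)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p_value - ex), 3 * mc$mc_se + 1e-3)
})

test_that("permutation test type-I error is near nominal under the null", {
  withr::local_seed(15)
  reject <- 0L; nrep <- 300L
  for (i in seq_len(nrep)) {
    x <- rnorm(6); y <- rnorm(6)
    if (permutation_test_two_sample(x, y)$p_value <= 0.05) reject <- reject + 1L
  }
  # binomial 3-sigma band around 0.05
  expect_lt(reject / nrep, 0.05 + 3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("pearson correlation matches cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  withr::local_seed(16)
  a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  got <- pearson_correlation(a, b)
  ref <- stats::cor.test(a, b)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "variance")
})
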