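test_that("loss-of-function classification separates LoF from missense", {
  expect_identical(lof_of(c("stop_gained", "frameshift", "splice_region",
                            "missense", "inframe_indel", NA)),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_false(lof_of("splice_region", lof_classes = c("stop_gained")))
})

test_that("the Poisson burden tail matches direct pmf summation", {
  # zero observations can never reject
  expect_equal(de_novo_burden(0, 5, 0.2)$p_value, 1.0)
  # P(X >= 3), X ~ Poisson(5 * 0.2 = 1), by direct summation
  direct <- 1 - sum(exp(-1) * 1^(0:2) / factorial(0:2))
  res <- de_novo_burden(3, 5, 0.2)
  expect_equal(res$p_value, direct, tolerance = 1e-12)
  expect_equal(res$observed_mean * res$n_samples, res$observed_total)
  expect_error(de_novo_burden(3, 5, 0), "expected_rate")
})

test_that("the burden p-value is monotone in the observation and the rate", {
  p_obs <- vapply(0:10, function(k) de_novo_burden(k, 6, 0.2)$p_value, 1)
  expect_true(all(diff(p_obs) <= 0))
  p_rate <- vapply(c(0.1, 0.2, 0.5, 1, 2),
                   function(r) de_novo_burden(4, 6, r)$p_value, 1)
  expect_true(all(diff(p_rate) >= 0))
})

test_that("the Monte-Carlo burden variant agrees with the analytic tail", {
  a <- de_novo_burden(4, 6, 0.2, method = "permutation",
                      n_permutations = 20000L, seed = 7L)
  b <- de_novo_burden(4, 6, 0.2, method = "permutation",
                      n_permutations = 20000L, seed = 7L)
  expect_identical(a$p_value, b$p_value)  # seeded, reproducible
  expect_lt(abs(a$p_value - de_novo_burden(4, 6, 0.2)$p_value), 0.005)
})

test_that("gene recurrence: degenerate inputs and analytic collision check", {
  expect_equal(gene_recurrence_test(character(), 1000)$p_value, 1)
  expect_equal(gene_recurrence_test(c("A", "B", "C"), 1000,
                                    n_permutations = 1000)$observed_recurrent, 0L)
  expect_equal(gene_recurrence_test(c("A", "B", "C"), 1000,
                                    n_permutations = 1000)$p_value, 1)
  # 5 calls all in one gene over a 10,000-gene universe: the null collision
  # probability is 1 - prod(1 - i/10^4) ~ 0.000999 (birthday bound)
  res <- gene_recurrence_test(rep("HERC1", 5), 10000L,
                              n_permutations = 10000L, seed = 11L)
  expect_equal(res$observed_recurrent, 1L)
  p_analytic <- 1 - prod(1 - (1:4) / 10000)
  expect_lt(abs(res$p_value - p_analytic), 1e-3)  # ~3 Monte-Carlo SDs
  expect_error(gene_recurrence_test(c("A", "B"), 1),
               "smaller than the number of distinct")
})

test_that("permutation p-values are reproducible and respect the add-one floor", {
  r1 <- gene_recurrence_test(c("A", "A", "B", "C"), 5000L,
                             n_permutations = 2000L, seed = 42L)
  r2 <- gene_recurrence_test(c("A", "A", "B", "C"), 5000L,
                             n_permutations = 2000L, seed = 42L)
  expect_identical(r1$p_value, r2$p_value)
  # an effectively unattainable statistic pins p at its minimum 1/(1+B)
  genes <- rep(sprintf("G%02d", 1:10), each = 2)
  r3 <- gene_recurrence_test(genes, 20000L, n_permutations = 1000L, seed = 1L)
  expect_equal(r3$p_value, 1 / 1001)
})

test_that("chi-squared matches direct computation and handles degenerate tables", {
  res <- proportion_chi2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 1L)
  # direct sum((O - E)^2 / E) oracle on random tables
  set.seed(2024)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    o <- proportion_chi2(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(o$chi2, sum((tab - e)^2 / e), tolerance = 1e-12)
    expect_equal(o$p_value, pchisq(o$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(proportion_chi2(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(proportion_chi2(matrix(1:6, 2)), "2x2")
})

test_that("chi-squared scales linearly with counts and ignores label order", {
  tab <- matrix(c(20, 5, 5, 20), 2)
  expect_equal(proportion_chi2(2 * tab)$chi2, 2 * proportion_chi2(tab)$chi2,
               tolerance = 1e-12)
  expect_equal(proportion_chi2(tab[2:1, ])$chi2, proportion_chi2(tab)$chi2)
  expect_equal(proportion_chi2(tab[, 2:1])$chi2, proportion_chi2(tab)$chi2)
  # optional continuity correction matches the textbook form
  yates <- proportion_chi2(tab, correct = TRUE)
  expect_lt(yates$chi2, proportion_chi2(tab)$chi2)
})

test_that("stats_report reproduces the planted burden conditions", {
  sc <- acceptance_cohort()
  sr <- stats_report(sc$pipe$candidates, sc$pipe$pedigree,
                     n_permutations = 1000L, seed = 5L)
  # 5 planted de novo per loss at 50% LoF mass: the observed mean should
  # sit near 2.5 per loss sample, far above the 0.2 background expectation
  expect_equal(sr$burden$n_samples, 12L)
  expect_gt(sr$burden$observed_mean, 1.5)
  expect_lt(sr$burden$p_value, 0.01)
  expect_lt(sr$recurrence$p_value, 0.05)  # several losses share planted genes?
  expect_true(all(sr$proportions$chi2 >= 0, na.rm = TRUE))
})
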