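test_that("Mann-Whitney U reproduces hand-enumerated exact cases", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 6)
  expect_match(r$method, "exact")
  ## identical multisets are exchangeable
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3), exact = "always")$p_value, 1)
  ## U(x,y) + U(y,x) = n1 * n2
  set.seed(51)
  for (i in 1:10) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(mann_whitney_u(x, y)$statistic + mann_whitney_u(y, x)$statistic,
                 length(x) * length(y))
  }
})

test_that("Wilcoxon signed-rank reproduces hand-enumerated exact cases", {
  r <- wilcoxon_signed_rank(1:5)
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 2 / 32)
  expect_equal(wilcoxon_signed_rank(1)$p_value, 1)
  ## negating all differences leaves p unchanged
  set.seed(52)
  for (i in 1:10) {
    d <- rnorm(8)
    expect_equal(wilcoxon_signed_rank(-d)$p_value, wilcoxon_signed_rank(d)$p_value)
  }
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "zero")
})

test_that("Spearman exact permutation p-values match small closed cases", {
  r3 <- spearman_exact(1:3, c(5, 7, 11))
  expect_equal(r3$statistic, 1)
  expect_equal(r3$p_value, 2 / 6)
  r5 <- spearman_exact(1:5, 2 * (1:5))
  expect_equal(r5$statistic, 1)
  expect_equal(r5$p_value, 2 / 120)
  ## reversing y flips rho, p unchanged
  set.seed(53)
  x <- rnorm(6); y <- rnorm(6)
  a <- spearman_exact(x, y); b <- spearman_exact(x, -y)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)
  expect_error(spearman_exact(rep(1, 5), rnorm(5)), "constant")
})

test_that("exact paths match base R where conventions coincide (no ties)", {
  set.seed(54)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(mann_whitney_u(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
    d <- rnorm(sample(4:10, 1))
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("Monte-Carlo Spearman p converges to the exact p", {
  set.seed(55)
  x <- rnorm(7); y <- 0.8 * x + rnorm(7, 0, 0.6)
  exact <- spearman_exact(x, y)$p_value
  mc <- spearman_exact(x, y, method = "montecarlo", mc_draws = 1e5, seed = 7L)
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(mc$p_value - exact), 2 * se + 2 / 1e5)
  expect_match(mc$method, "seed 7")
})

test_that("Cohen's d uses the pooled SD and the patient-minus-control sign", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2), c(2, 4)), -2 / sqrt(2))
  set.seed(56)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y))
  expect_lt(cohens_d(x - 5, y), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 4)), "pooled")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("midrank ties are handled exactly under the forced-exact path", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  expect_equal(mann_whitney_u(x, y, exact = "always")$p_value, oracle_mw_p(x, y))
  d <- c(1, -1, 2, 2, -3)
  expect_equal(wilcoxon_signed_rank(d, exact = "always")$p_value, oracle_wsrt_p(d))
})
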