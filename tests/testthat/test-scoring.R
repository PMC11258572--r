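test_that("RPQ totals and factor subscores follow the three-factor structure", {
  expect_equal(score_rpq(rep(4L, 16))$total, 64)
  zero <- score_rpq(rep(0L, 16))
  expect_equal(zero$total, 0)
  expect_equal(zero$cognitive + zero$somatic + zero$emotional, 0)
  expect_length(zero$qualifying_items, 0)

  fm <- rpq_factor_map()
  expect_setequal(fm$factor[fm$index %in% c(10, 11, 12)], "cognitive")
  items <- rep(0L, 16); items[c(10, 11, 12)] <- 4L
  s <- score_rpq(items)
  expect_equal(s$cognitive, 12)   # observed factor maximum
  expect_equal(s$total, 12)
  expect_equal(s$somatic, 0)

  set.seed(41)
  items <- sample(0:4, 16, replace = TRUE)
  s <- score_rpq(items)
  expect_equal(s$total, sum(items))
  expect_equal(s$cognitive + s$somatic + s$emotional, s$total)
  expect_lte(s$cognitive, 12)
  expect_lte(s$emotional, 16)
  expect_setequal(s$qualifying_items, which(items > 1))
})

test_that("RPQ total is invariant to permuting items within a factor", {
  set.seed(42)
  items <- sample(0:4, 16, replace = TRUE)
  s0 <- score_rpq(items)
  fm <- rpq_factor_map()
  som <- fm$index[fm$factor == "somatic"]
  items2 <- items
  items2[som] <- items[sample(som)]
  s1 <- score_rpq(items2)
  expect_equal(s1$total, s0$total)
  expect_equal(s1$somatic, s0$somatic)
  expect_equal(s1$cognitive, s0$cognitive)
})

test_that("RPQ rejects malformed input", {
  expect_error(score_rpq(rep(2L, 15)), "16")
  expect_error(score_rpq(c(rep(1L, 15), 5L)), "0-4")
  expect_error(score_rpq(c(rep(1L, 15), -1L)), "0-4")
})

test_that("BTACT z-scores standardize against the norms", {
  norms <- list(mean = rep(3, 6), sd = rep(2, 6))
  at_norm <- score_btact(rep(3, 6), norms)
  expect_equal(at_norm$subtest_z, rep(0, 6))
  expect_equal(at_norm$composite_z, 0)
  plus1 <- score_btact(norms$mean + norms$sd, norms)
  expect_equal(plus1$composite_z, 1)
  s <- score_btact(1:6, norms)
  expect_equal(s$subtest_z, c(-1, -0.5, 0, 0.5, 1, 1.5))
  expect_equal(s$composite_z, 0.25)
})

test_that("missing BTACT subtests follow the imputation policy", {
  norms <- list(mean = rep(0, 6), sd = rep(1, 6))
  raw <- c(1, 1, NA, 1, 1, 1)
  expect_true(is.na(score_btact(raw, norms)$composite_z))
  expect_equal(score_btact(raw, norms, impute_policy = "available")$composite_z, 1)
  expect_error(score_btact(rep(1, 6), list(mean = rep(0, 6), sd = rep(0, 6))),
               "positive")
})

test_that("GOSE dichotomization marks only complete recovery", {
  expect_true(dichotomize_gose(8L))
  expect_identical(dichotomize_gose(3:8), c(rep(FALSE, 5), TRUE))
  expect_error(dichotomize_gose(2L), "3-8")
  expect_error(dichotomize_gose(9L), "3-8")
})

test_that("rates of change are signed per-day differences", {
  expect_equal(rate_of_change(5, 5, 30), 0)
  expect_equal(rate_of_change(38.6, 35.0, 90), 0.04)
  expect_equal(rate_of_change(3, 7, 10), -0.4)
  expect_equal(rate_of_change(3, 7, 10, absolute = TRUE), 0.4)
  expect_equal(rate_of_change(10, 4, 12), -rate_of_change(4, 10, 12))
  expect_error(rate_of_change(1, 2, 0), "positive")
})

test_that("cohort scoring appends totals, z-scores and recovery status", {
  co <- generate_cohort(cohort_design(n_patients = 6L, n_controls = 4L, seed = 9L))
  sc <- score_cohort(co)
  rpq_cols <- paste0("rpq_", sprintf("%02d", 1:16))
  expect_equal(sc$rpq_total, rowSums(sc[rpq_cols]))
  expect_equal(sc$recovered, sc$gose == 8L)
  expect_true(all(is.na(sc$recovered[sc$group == "control"])))
  expect_equal(sc$btact_composite, rowMeans(sc[paste0("btact_z", 1:6)]))
})
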