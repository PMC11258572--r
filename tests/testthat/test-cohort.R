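test_that("generated cohorts satisfy the schema invariants", {
  co <- generate_cohort()
  expect_s3_class(co, "na_cohort")
  expect_silent(validate_cohort(co))
  expect_equal(sum(co$group == "patient" & co$visit == "v1"), 27)
  expect_equal(sum(co$group == "patient" & co$visit == "v2"), 20)
  expect_equal(sum(co$group == "patient" & co$visit == "v3"), 15)
  expect_equal(sum(co$group == "control"), 21)
  expect_equal(sum(co$visit == "v2" & !is.na(co$atsc_gm)), 17)
  expect_true(all(is.na(co$atsc_gm[co$visit == "v3"])))
  expect_true(all(is.na(co$days_from_injury[co$group == "control"])))
  rpq <- as.matrix(co[paste0("rpq_", sprintf("%02d", 1:16))])
  expect_true(all(rpq %in% 0:4))
  expect_true(all(co$gose[co$group == "patient"] %in% 3:8))
})

test_that("cohort generation is deterministic in the design seed", {
  a <- generate_cohort(cohort_design(seed = 7L))
  b <- generate_cohort(cohort_design(seed = 7L))
  c2 <- generate_cohort(cohort_design(seed = 8L))
  expect_identical(a, b)
  expect_false(identical(a$atsc_gm, c2$atsc_gm))
})

test_that("degenerate designs are rejected", {
  expect_error(cohort_design(retention_v2 = 1.2), "retention")
  expect_error(cohort_design(gm_sd = -1), "standard deviations")
  expect_error(cohort_design(coupling = 1.5), "coupling")
  expect_error(cohort_design(n_patients = 0), "group sizes")
})

test_that("null design yields no group difference and independence", {
  d <- cohort_design(n_patients = 5000L, n_controls = 5000L,
                     deficit_gm_sd = 0, deficit_wm_sd = 0, coupling = 0,
                     rate_gm_mean = 0, rate_wm_mean = 0,
                     recovery_tau_days = Inf, seed = 13L)
  co <- generate_cohort(d)
  v1 <- co[co$visit == "v1", ]
  pat <- v1$atsc_gm[v1$group == "patient"]
  ctl <- v1$atsc_gm[v1$group == "control"]
  se <- sqrt(var(pat) / length(pat) + var(ctl) / length(ctl))
  expect_lt(abs(mean(pat) - mean(ctl)), 3 * se)
  ## moments match the design within Monte-Carlo error
  expect_lt(abs(mean(pat) - 35), 3 * sd(pat) / sqrt(length(pat)))
  expect_lt(abs(sd(pat) - 1.8), 0.1)
  ## coupling 0: aTSC carries no information about symptoms
  sc <- score_cohort(co)
  p1 <- sc[sc$group == "patient" & sc$visit == "v1", ]
  expect_lt(abs(cor(p1$atsc_gm, p1$rpq_total, method = "spearman")),
            3 / sqrt(nrow(p1)))
})

test_that("configured deficit and recovery rate appear in the generated data", {
  d <- cohort_design(seed = 17L)
  co <- generate_cohort(d)
  v1 <- co[co$visit == "v1", ]
  gap <- mean(v1$atsc_gm[v1$group == "control"]) -
    mean(v1$atsc_gm[v1$group == "patient"])
  expect_gt(gap, 1.8 * 2 - 1.5)  # deficit of 2 control SDs, wide tolerance
  ## per-subject realized v2-v1 GM rates center on the design rate
  p <- co[co$group == "patient", ]
  m <- merge(p[p$visit == "v1", c("subject_id", "atsc_gm", "days_from_injury")],
             p[p$visit == "v2", c("subject_id", "atsc_gm", "days_from_injury")],
             by = "subject_id")
  m <- m[!is.na(m$atsc_gm.y), ]
  rates <- (m$atsc_gm.y - m$atsc_gm.x) / (m$days_from_injury.y - m$days_from_injury.x)
  expect_lt(abs(mean(rates) - 0.04), 3 * sd(rates) / sqrt(length(rates)) + 0.01)
})

test_that("the configured 2-SD deficit reproduces a Cohen's d near -2", {
  ds <- vapply(1:200, function(i) {
    co <- generate_cohort(cohort_design(seed = 1000L + i))
    v1 <- co[co$visit == "v1", ]
    cohens_d(v1$atsc_gm[v1$group == "patient"], v1$atsc_gm[v1$group == "control"])
  }, 0)
  expect_lt(abs(mean(ds) - (-2.0)), 0.15)
})
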