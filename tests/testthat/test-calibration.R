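raw_stub <- function(values, bg_idx = NULL, eye_idx = NULL) {
  n <- length(values)
  structure(list(signal = array(values, c(n, 1, 1)),
                 affine = diag(4),
                 background_region = bg_idx,
                 eye_regions = eye_idx),
            class = "na_raw")
}

test_that("noise SD is the n-1 sample SD over the background region", {
  v <- raw_stub(c(1, 2, 3, 4), bg_idx = cbind(1:4, 1L, 1L))
  expect_equal(estimate_noise_sd(v), sd(1:4))
  expect_equal(estimate_noise_sd(v), 1.290994, tolerance = 1e-6)
  const <- raw_stub(rep(7, 5), bg_idx = cbind(1:5, 1L, 1L))
  expect_equal(estimate_noise_sd(const), 0)
  tiny <- raw_stub(1, bg_idx = cbind(1L, 1L, 1L))
  expect_error(estimate_noise_sd(tiny), "at least 2")
})

test_that("two-anchor fit maps noise to 0 mM and the eye to 140 mM", {
  m <- fit_calibration(noise_sd = 2, eye_mean = 72)
  expect_equal(m$slope * 72 + m$intercept, 140, tolerance = 1e-9)
  expect_equal(m$slope * 2 + m$intercept, 0, tolerance = 1e-9)
  expect_equal(m$slope * 37 + m$intercept, 70, tolerance = 1e-9)
  expect_gt(m$slope, 0)
  expect_error(fit_calibration(noise_sd = 5, eye_mean = 5), "exceed")
  expect_error(fit_calibration(noise_sd = 5, eye_mean = 3), "exceed")
})

test_that("applying calibration clamps negatives only when asked", {
  m <- fit_calibration(noise_sd = 2, eye_mean = 72)
  v <- raw_stub(c(0, 1, 2, 37, 72))
  clamped <- apply_calibration(v, m)$data
  expect_true(all(clamped >= 0))
  expect_equal(as.numeric(clamped)[4:5], c(70, 140))
  free <- apply_calibration(v, m, clamp_negative = FALSE)$data
  expect_lt(free[1], 0)
  zero <- apply_calibration(raw_stub(rep(0, 3)), fit_calibration(0, 10))$data
  expect_true(all(zero == 0))
})

test_that("calibration is invariant to a common rescaling of signal and anchors", {
  set.seed(21)
  values <- runif(50, 0, 100)
  m1 <- fit_calibration(noise_sd = 3, eye_mean = 80)
  a <- 7.3
  m2 <- fit_calibration(noise_sd = 3 * a, eye_mean = 80 * a)
  map1 <- apply_calibration(raw_stub(values), m1, clamp_negative = FALSE)$data
  map2 <- apply_calibration(raw_stub(values * a), m2, clamp_negative = FALSE)$data
  expect_equal(map1, map2, tolerance = 1e-9)
})

test_that("zero-noise round trip recovers 140 mM in the eye region", {
  ph <- demo_phantom()
  raw <- simulate_acquisition(ph)
  img <- calibrate_volume(raw)          # plain two-anchor calibration
  eye_idx <- do.call(rbind, raw$eye_regions)
  eye_mean <- mean(img$data[cbind(eye_idx)])
  expect_lt(abs(eye_mean - 140) / 140, 0.001)
})

test_that("eye reference statistic supports retention correction", {
  v <- raw_stub(c(90, 110), eye_idx = list(left = cbind(1L, 1L, 1L),
                                           right = cbind(2L, 1L, 1L)))
  expect_equal(eye_reference_signal(v), 100)
  expect_equal(eye_reference_signal(v, retention = 0.8), 125)
  expect_error(eye_reference_signal(v, retention = 1.4), "retention")
})
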