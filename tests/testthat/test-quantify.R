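frac3 <- function(fg, fw, fc = rep(0, length(fg))) {
  n <- length(fg)
  new_fractions(array(fg, c(n, 1, 1)), array(fw, c(n, 1, 1)),
                array(fc, c(n, 1, 1)), diag(4))
}

test_that("regridding block-averages fractions and conserves tissue volume", {
  ph <- demo_phantom()
  lo <- regrid_fractions(ph$fractions, c(6, 6, 6))
  expect_identical(dim(lo$f_gm), dim(ph$fractions$f_gm) %/% 3L)
  ## volume conservation: fraction x voxel volume summed
  v_hi <- sum(ph$fractions$f_gm) * 2^3
  v_lo <- sum(lo$f_gm) * 6^3
  expect_lt(abs(v_hi - v_lo) / v_hi, 1e-6)
  total <- lo$f_gm + lo$f_wm + lo$f_csf
  expect_lte(max(total), 1 + 1e-9)
  ## identity target grid
  same <- regrid_fractions(ph$fractions, c(2, 2, 2))
  expect_identical(same$f_gm, ph$fractions$f_gm)
  ## hand-computed block mean
  f <- new_fractions(array(c(1, 0, 0, 0, 1, 1, 0, 1), c(2, 2, 2)),
                     array(0, c(2, 2, 2)), array(0, c(2, 2, 2)),
                     centered_affine_for_test(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(as.numeric(regrid_fractions(f, 2)$f_gm), 0.5)
})

test_that("constant fraction fields survive regridding and smoothing unchanged", {
  f <- new_fractions(array(0.4, c(12, 12, 12)), array(0.3, c(12, 12, 12)),
                     array(0.2, c(12, 12, 12)),
                     centered_affine_for_test(c(2, 2, 2), c(12, 12, 12)))
  lo <- regrid_fractions(f, 6)
  expect_equal(as.numeric(lo$f_gm), rep(0.4, 64), tolerance = 1e-12)
  k <- build_psf_kernel(56, 36.3, voxel_mm = 6, size = 3)
  sm <- smooth_fractions(lo, k)
  expect_equal(sm$f_gm, lo$f_gm, tolerance = 1e-9)
})

test_that("trilinear regridding handles non-nested grids and stays in range", {
  ph <- demo_phantom()
  tri <- regrid_fractions(ph$fractions, c(5, 5, 5), resample = "trilinear")
  expect_true(all(tri$f_gm >= 0 & tri$f_gm <= 1))
  expect_lte(max(tri$f_gm + tri$f_wm + tri$f_csf), 1 + 1e-9)
  expect_error(regrid_fractions(ph$fractions, c(5, 5, 5)), "trilinear")
})

test_that("PSF smoothing is the identity for a delta kernel and halves a step edge", {
  ph <- demo_phantom()
  lo <- regrid_fractions(ph$fractions, c(6, 6, 6))
  sm <- smooth_fractions(lo, delta_kernel(3))
  expect_equal(sm$f_gm, lo$f_gm, tolerance = 1e-12)
  ## symmetric kernel on a step edge: values across the edge sum to 1
  n <- 16
  step <- array(rep(c(0, 1), each = n / 2 * n * n), c(n, n, n))
  step <- aperm(step, c(3, 2, 1))  # step along the first axis
  g <- build_psf_kernel(56, 36.3, voxel_mm = 6, size = 5, kernel_mode = "gaussian")
  f <- new_fractions(step, 0 * step, 0 * step,
                     centered_affine_for_test(c(6, 6, 6), dim(step)))
  smoothed <- smooth_fractions(f, g)$f_gm
  mid <- n / 2
  expect_equal(smoothed[mid, 8, 8] + smoothed[mid + 1, 8, 8], 1, tolerance = 1e-9)
  expect_error(smooth_fractions(lo, delta_kernel(3) * 2), "normalized")
})

test_that("the 3-voxel noiseless system is solved exactly", {
  fr <- frac3(c(1, 0, 0.5), c(0, 1, 0.5))
  est <- solve_global_atsc(array(c(35, 30, 32.5), c(3, 1, 1)), fr, csf_mM = 0)
  expect_equal(est$atsc_gm, 35, tolerance = 1e-10)
  expect_equal(est$atsc_wm, 30, tolerance = 1e-10)
  expect_equal(est$residual_rms, 0, tolerance = 1e-10)
  expect_identical(est$n_voxels_used, 3L)
  expect_gt(est$design_condition_number, 0)
})

test_that("fixed-concentration CSF term is subtracted before solving", {
  fr <- frac3(c(0.8, 0.1), c(0.1, 0.7), c(0.1, 0.2))
  obs <- 0.8 * 40 + 0.1 * 25 + 0.1 * 140
  obs2 <- 0.1 * 40 + 0.7 * 25 + 0.2 * 140
  est <- solve_global_atsc(array(c(obs, obs2), c(2, 1, 1)), fr, csf_mM = 140)
  expect_equal(est$atsc_gm, 40, tolerance = 1e-8)
  expect_equal(est$atsc_wm, 25, tolerance = 1e-8)
})

test_that("degenerate designs are rejected with diagnostics", {
  single <- frac3(c(0.9, 0.5, 0.7), c(0, 0, 0))
  expect_error(solve_global_atsc(array(1:3, c(3, 1, 1)), single),
               "rank-deficient|condition")
  prop <- frac3(c(0.6, 0.4, 0.2), c(0.3, 0.2, 0.1))
  expect_error(solve_global_atsc(array(1:3, c(3, 1, 1)), prop),
               "rank-deficient")
  fr <- frac3(c(0.1, 0.1), c(0.1, 0.1))  # nothing passes the 0.5 mask
  expect_error(solve_global_atsc(array(c(1, 2), c(2, 1, 1)), fr), "mask")
})

test_that("least squares agrees with an explicit normal-equations oracle", {
  set.seed(31)
  for (n in c(10, 200, 1000)) {
    fg <- runif(n); fw <- pmin(runif(n), 1 - fg)
    fc <- pmin(runif(n, 0, 0.3), 1 - fg - fw)
    y <- 35 * fg + 30 * fw + 140 * fc + rnorm(n, 0, 0.5)
    fr <- frac3(fg, fw, fc)
    est <- solve_global_atsc(array(y, c(n, 1, 1)), fr,
                             mask_rule = function(g, w, c) g + w + c > -1)
    X <- cbind(fg, fw)
    beta <- solve(t(X) %*% X, t(X) %*% (y - 140 * fc))
    expect_equal(est$atsc_gm, beta[1], tolerance = 1e-8)
    expect_equal(est$atsc_wm, beta[2], tolerance = 1e-8)
  }
})

test_that("raising the true GM concentration raises the GM estimate", {
  ests <- vapply(c(30, 35, 40), function(cg) {
    tr <- phantom_truth(c_gm = cg)
    ph <- generate_phantom(phantom_geometry_demo(), tr)
    raw <- simulate_acquisition(ph)
    quantify_volume(raw, ph$fractions, f_eye = ph$f_eye)$atsc_gm
  }, 0)
  expect_true(all(diff(ests) > 0))
})

test_that("tissue aTSC is robust to doubling the ventricle volume", {
  est_for <- function(scale) {
    geom <- phantom_geometry(vent_semi = c(15, 8, 8) * scale)
    ph <- generate_phantom(geom, phantom_truth())
    raw <- simulate_acquisition(ph)
    quantify_volume(raw, ph$fractions, f_eye = ph$f_eye)
  }
  base <- est_for(1)
  doubled <- est_for(2^(1 / 3))
  expect_lt(abs(doubled$atsc_gm - base$atsc_gm) / base$atsc_gm, 0.02)
  expect_lt(abs(doubled$atsc_wm - base$atsc_wm) / base$atsc_wm, 0.02)
})

test_that("normalized ventricular volume is the eTIV-scaled bilateral sum", {
  expect_equal(normalized_ventricular_volume(5000, 5000, 1e6), 0.01)
  expect_equal(normalized_ventricular_volume(0, 0, 1e6), 0)
  a <- normalized_ventricular_volume(4321, 5678, 1.4e6)
  b <- normalized_ventricular_volume(4.321, 5.678, 1.4e3)
  expect_equal(a, b)
  expect_error(normalized_ventricular_volume(1, 1, 0), "positive")
  expect_error(normalized_ventricular_volume(-1, 1, 10), ">= 0")
})
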