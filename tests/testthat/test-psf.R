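test_that("PSF kernel is normalized, finite and symmetric under axis reflection", {
  for (params in list(c(56, 36.3), c(56, 10), c(20, 50))) {
    k <- build_psf_kernel(params[1], params[2], voxel_mm = 6, size = 9)
    expect_true(all(is.finite(k)))
    expect_lt(abs(sum(k) - 1), 1e-9)
    expect_equal(k, k[dim(k)[1]:1, , ], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(k, k[, dim(k)[2]:1, ], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(k, k[, , dim(k)[3]:1], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(aperm(k, c(2, 1, 3)), k, tolerance = 1e-12,
                 ignore_attr = TRUE)  # isotropic grid
  }
})

test_that("no-decay limit approaches a discrete delta", {
  k <- build_psf_kernel(1e9, 36.3, voxel_mm = 6, size = 9)
  expect_gt(max(k), 1 - 1e-6)
  expect_equal(which.max(k), (prod(dim(k)) + 1) %/% 2)
})

test_that("longer readout widens the kernel main lobe", {
  f_long <- attr(build_psf_kernel(56, 36.3, voxel_mm = 6), "fwhm_mm")
  f_short <- attr(build_psf_kernel(56, 10, voxel_mm = 6), "fwhm_mm")
  expect_gt(f_long, f_short)
})

test_that("gaussian mode matches the exponential kernel's FWHM", {
  ke <- build_psf_kernel(56, 36.3, voxel_mm = 2, nominal_mm = 6, size = 31)
  kg <- build_psf_kernel(56, 36.3, voxel_mm = 2, nominal_mm = 6, size = 31,
                         kernel_mode = "gaussian")
  expect_lt(abs(sum(kg) - 1), 1e-9)
  expect_true(all(kg >= 0))
  expect_equal(attr(kg, "fwhm_mm"), attr(ke, "fwhm_mm"), tolerance = 0.15)
})

test_that("invalid PSF parameters are rejected", {
  expect_error(build_psf_kernel(0, 36.3, 6), "t2_ms")
  expect_error(build_psf_kernel(-5, 36.3, 6), "t2_ms")
  expect_error(build_psf_kernel(56, 36.3, 6, size = 8), "odd")
})

test_that("edge-padded convolution preserves constant fields", {
  k <- build_psf_kernel(56, 36.3, voxel_mm = 6, size = 7)
  x <- array(3.7, c(12, 10, 11))
  expect_equal(convolve3d(x, k), x, tolerance = 1e-9)
})

test_that("convolution with a delta kernel is the identity", {
  set.seed(11)
  x <- array(rnorm(8 * 9 * 10), c(8, 9, 10))
  expect_equal(convolve3d(x, delta_kernel(3)), x, tolerance = 1e-12)
})

test_that("FFT convolution matches direct convolution on a small case", {
  set.seed(12)
  x <- array(rnorm(6 * 6 * 6), c(6, 6, 6))
  k <- array(runif(27), c(3, 3, 3)); k <- k / sum(k)
  ## direct edge-padded convolution oracle
  pad <- function(i, n) pmin(pmax(i, 1L), n)
  direct <- array(0, dim(x))
  for (i in 1:6) for (j in 1:6) for (l in 1:6) {
    acc <- 0
    for (a in -1:1) for (b in -1:1) for (cc in -1:1)
      acc <- acc + k[2 - a, 2 - b, 2 - cc] *
        x[pad(i + a, 6L), pad(j + b, 6L), pad(l + cc, 6L)]
    direct[i, j, l] <- acc
  }
  expect_equal(convolve3d(x, k), direct, tolerance = 1e-10)
})
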