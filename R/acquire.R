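#' Block-average a high-resolution volume onto a coarser grid
#'
#' Each low-resolution voxel is the mean of the \code{factor[1] x factor[2] x
#' factor[3]} block of high-resolution voxels it covers; grids must nest
#' exactly.
#'
#' @param x 3-D array.
#' @param factor Integer downsampling factor per axis (scalar or length 3).
#' @return Array of shape \code{dim(x)/factor}.
#' @export
block_average <- function(x, factor) {
  if (length(factor) == 1L) factor <- rep(factor, 3L)
  factor <- as.integer(factor)
  d <- dim(x)
  if (any(d %% factor != 0L))
    stop(sprintf(paste("grid %s is not an integer multiple of the block factor %s;",
                       "use resample = 'trilinear' for non-nested grids"),
                 paste(d, collapse = "x"), paste(factor, collapse = "x")))
  out_d <- d %/% factor
  dim(x) <- c(factor[1], out_d[1], factor[2], out_d[2], factor[3], out_d[3])
  x <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(x) <- c(prod(factor), prod(out_d))
  out <- colMeans(x)
  dim(out) <- out_d
  out
}

#' Simulate a raw sodium acquisition from a phantom
#'
#' Applies the forward model of a low-resolution sodium scan to the phantom's
#' noiseless concentration field: (1) convolution with the T2-decay PSF
#' sampled at the high resolution, (2) block-averaging down to the sodium
#' grid, (3) a fixed gain from mM to arbitrary signal units, (4) Rician (or
#' Gaussian) noise with the truth's \code{noise_sigma} and \code{seed}. The
#' background noise region (560 voxels from the corner of the central slice by
#' default) and the two eroded eye reference regions are recorded in the
#' output.
#'
#' @param phantom An \code{\link{generate_phantom}} result.
#' @param kernel Optional PSF kernel override (e.g. \code{\link{delta_kernel}()});
#'   by default built from the truth's T2/readout at the high resolution with
#'   \code{k_max} at the nominal sodium resolution.
#' @param background_size Number of background voxels to record (default 560).
#' @return Object of class \code{"na_raw"}: \code{signal} (lo-res array),
#'   \code{affine}, \code{background_region} and \code{eye_regions} (integer
#'   voxel-index matrices), \code{truth}, \code{noiseless} (pre-noise signal).
#' @export
simulate_acquisition <- function(phantom, kernel = NULL, background_size = 560L) {
  stopifnot(inherits(phantom, "na_phantom"))
  truth <- phantom$truth
  ratio <- truth$lo_res_voxel_mm / truth$hi_res_voxel_mm
  if (max(abs(ratio - round(ratio))) > 1e-9)
    stop(paste("lo_res_voxel_mm is not an integer multiple of hi_res_voxel_mm;",
               "block-averaging needs nested grids"))
  ratio <- as.integer(round(ratio))
  if (is.null(kernel))
    kernel <- build_psf_kernel(truth$t2_ms, truth$readout_ms,
                               voxel_mm = truth$hi_res_voxel_mm,
                               nominal_mm = max(truth$lo_res_voxel_mm))
  blurred <- convolve3d(phantom$concentration, kernel)
  lo <- block_average(blurred, ratio)
  lo_shape <- dim(lo)
  affine <- centered_affine(truth$lo_res_voxel_mm, lo_shape)
  noiseless <- truth$gain * lo

  eye_regions <- eye_reference_regions(phantom, ratio, lo_shape)
  background <- background_corner_region(noiseless, background_size,
                                         exclude = do.call(rbind, eye_regions))

  signal <- with_seed(truth$seed, add_acquisition_noise(noiseless,
                                                        truth$noise_sigma,
                                                        truth$noise_model))
  structure(list(signal = signal, affine = affine,
                 background_region = background, eye_regions = eye_regions,
                 truth = truth, noiseless = noiseless),
            class = "na_raw")
}

## Rician: magnitude of (s + n1) + i n2; Gaussian: s + n1.
add_acquisition_noise <- function(s, sigma, model) {
  if (sigma == 0) return(s)
  n <- length(s)
  if (model == "rician") {
    out <- sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  } else {
    out <- s + stats::rnorm(n, 0, sigma)
  }
  dim(out) <- dim(s)
  out
}

## lo-res voxels that are entirely vitreous and whose centres lie within
## radius - erosion of an eye centre, keeping the reference clear of PSF
## losses at the eye boundary
eye_reference_regions <- function(phantom, ratio, lo_shape) {
  geom <- phantom$geometry
  full_lo <- block_average(phantom$f_eye, ratio)
  affine_lo <- centered_affine(phantom$truth$lo_res_voxel_mm, lo_shape)
  co <- axis_coords(affine_lo, lo_shape)
  ca <- coord_arrays(co[[1]], co[[2]], co[[3]])
  rmax <- geom$eye_radius_mm - geom$eye_erosion_mm
  pick_side <- function(center) {
    d <- sqrt((ca$X - center[1])^2 + (ca$Y - center[2])^2 + (ca$Z - center[3])^2)
    idx <- which(full_lo >= 1 - 1e-9 & d <= rmax + 1e-9, arr.ind = TRUE)
    if (nrow(idx) == 0)
      stop(paste("no low-resolution voxel qualifies as eye reference;",
                 "enlarge eye_radius_mm or reduce eye_erosion_mm"))
    unname(idx)
  }
  ec <- geom$eye_center
  list(left = pick_side(ec * c(-1, 1, 1)), right = pick_side(ec))
}

## Greedy corner block: walk slices outward from the central slice and, within
## each, voxels by Chebyshev distance from the (1,1) in-plane corner, keeping
## signal-free voxels (residual blurred signal below 0.1% of the image
## maximum) until `size` are collected.
background_corner_region <- function(noiseless, size, exclude = NULL) {
  d <- dim(noiseless)
  size <- as.integer(size)
  if (size < 2) stop("background region needs at least 2 voxels")
  thresh <- 1e-3 * max(noiseless)
  zc <- (d[3] + 1L) %/% 2L
  z_order <- order(abs(seq_len(d[3]) - zc), seq_len(d[3]))
  ij <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2])))
  ij <- ij[order(pmax(ij[, 1], ij[, 2]), ij[, 1] + ij[, 2], ij[, 1]), , drop = FALSE]
  excl_key <- if (is.null(exclude)) character(0) else
    paste(exclude[, 1], exclude[, 2], exclude[, 3])
  picked <- matrix(0L, 0, 3)
  for (z in z_order) {
    free <- noiseless[cbind(ij[, 1], ij[, 2], z)] <= thresh
    cand <- cbind(ij[free, , drop = FALSE], z)
    if (length(excl_key))
      cand <- cand[!(paste(cand[, 1], cand[, 2], cand[, 3]) %in% excl_key), ,
                   drop = FALSE]
    need <- size - nrow(picked)
    if (need <= 0) break
    picked <- rbind(picked, cand[seq_len(min(need, nrow(cand))), , drop = FALSE])
  }
  if (nrow(picked) < size)
    stop(sprintf("only %d signal-free background voxels available (need %d)",
                 nrow(picked), size))
  colnames(picked) <- NULL
  unname(picked[seq_len(size), , drop = FALSE])
}

#' @export
print.na_raw <- function(x, ...) {
  cat("Raw sodium volume\n")
  cat(sprintf("  grid %s at %s mm, noise %s sigma=%.4g\n",
              paste(dim(x$signal), collapse = "x"),
              paste(x$truth$lo_res_voxel_mm, collapse = "x"),
              x$truth$noise_model, x$truth$noise_sigma))
  cat(sprintf("  background voxels: %d; eye voxels: %d + %d\n",
              nrow(x$background_region), nrow(x$eye_regions$left),
              nrow(x$eye_regions$right)))
  invisible(x)
}
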