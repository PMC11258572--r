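#' Regrid tissue-fraction maps onto a coarser target grid
#'
#' Volume-weighted averaging of each fraction field onto the target grid.
#' When the grids nest exactly (target voxel size an integer multiple of the
#' source), exact block-averaging is used and total tissue volume is
#' conserved; otherwise trilinear interpolation at target voxel centres is
#' available as an approximation.
#'
#' @param fractions An \code{"na_fractions"} triple.
#' @param target_voxel_mm Target voxel size (scalar or length 3).
#' @param target_shape Target grid dimensions; defaults to
#'   \code{source_shape / factor} for nested grids.
#' @param resample \code{"block"} (default, nested grids only) or
#'   \code{"trilinear"}.
#' @return An \code{"na_fractions"} object on the target grid.
#' @export
regrid_fractions <- function(fractions, target_voxel_mm, target_shape = NULL,
                             resample = c("block", "trilinear")) {
  stopifnot(inherits(fractions, "na_fractions"))
  resample <- match.arg(resample)
  if (length(target_voxel_mm) == 1L) target_voxel_mm <- rep(target_voxel_mm, 3L)
  src_vox <- diag(fractions$affine)[1:3]
  if (resample == "block") {
    ratio <- target_voxel_mm / src_vox
    if (max(abs(ratio - round(ratio))) > 1e-9)
      stop("target grid does not nest in the source grid; use resample = 'trilinear'")
    ratio <- as.integer(round(ratio))
    if (all(ratio == 1L)) return(fractions)
    out <- lapply(fractions[c("f_gm", "f_wm", "f_csf")], block_average, factor = ratio)
    shape <- dim(out$f_gm)
  } else {
    if (is.null(target_shape))
      target_shape <- as.integer(round(fractions$grid_shape * src_vox / target_voxel_mm))
    out <- lapply(fractions[c("f_gm", "f_wm", "f_csf")], trilinear_resample,
                  src_affine = fractions$affine,
                  target_affine = centered_affine(target_voxel_mm, target_shape),
                  target_shape = target_shape)
    shape <- target_shape
  }
  new_fractions(out$f_gm, out$f_wm, out$f_csf,
                centered_affine(target_voxel_mm, shape))
}

## trilinear interpolation of a 3-D field at the target grid's voxel centres
trilinear_resample <- function(x, src_affine, target_affine, target_shape) {
  src_shape <- dim(x)
  src_co <- axis_coords(src_affine, src_shape)
  tgt_co <- axis_coords(target_affine, target_shape)
  ## fractional source index per target coordinate, clamped to the volume
  fi <- lapply(1:3, function(a) {
    i <- (tgt_co[[a]] - src_co[[a]][1]) / (src_co[[a]][2] - src_co[[a]][1]) + 1
    pmin(pmax(i, 1), src_shape[a])
  })
  lo <- lapply(1:3, function(a) pmin(floor(fi[[a]]), src_shape[a] - 1))
  w <- lapply(1:3, function(a) fi[[a]] - lo[[a]])
  out <- array(0, target_shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 1) w[[1]] else 1 - w[[1]]
    wy <- if (dy == 1) w[[2]] else 1 - w[[2]]
    wz <- if (dz == 1) w[[3]] else 1 - w[[3]]
    ww <- coord_arrays(wx, wy, wz)
    ii <- coord_arrays(lo[[1]] + dx, lo[[2]] + dy, lo[[3]] + dz)
    out <- out + ww$X * ww$Y * ww$Z *
      x[cbind(as.vector(ii$X), as.vector(ii$Y), as.vector(ii$Z))]
  }
  out
}

#' Smooth tissue-fraction maps with the acquisition PSF
#'
#' Convolves each fraction field with the same normalized kernel, so the
#' design of the partial-volume regression sees tissue the way the sodium
#' image does and CSF spill-over is counteracted rather than attributed to
#' tissue. A convex combination of fields stays a convex combination, so
#' fraction invariants are preserved.
#'
#' @param fractions An \code{"na_fractions"} triple.
#' @param kernel Normalized 3-D kernel (sums to 1).
#' @return Smoothed \code{"na_fractions"}.
#' @export
smooth_fractions <- function(fractions, kernel) {
  stopifnot(inherits(fractions, "na_fractions"))
  if (abs(sum(kernel) - 1) > 1e-6)
    stop("kernel must be normalized (sum 1)")
  sm <- lapply(fractions[c("f_gm", "f_wm", "f_csf")], convolve3d, kern = kernel)
  clip01 <- function(x) pmin(pmax(x, 0), 1)  # guard fp undershoot of sinc lobes
  new_fractions(clip01(sm$f_gm), clip01(sm$f_wm), clip01(sm$f_csf),
                fractions$affine)
}

#' Solve for global GM and WM aTSC by partial-volume regression
#'
#' Over all brain voxels passing the mask rule, solves the over-determined
#' linear system
#' \deqn{obs_v - f_{csf,v} \cdot c_{CSF} = f_{gm,v} \cdot aTSC_{GM} + f_{wm,v} \cdot aTSC_{WM}}
#' by ordinary least squares for the two unknowns, the apparent total sodium
#' concentrations of global grey and white matter.
#'
#' @param image An \code{"na_image"} calibrated volume (or list with a
#'   \code{data} array in mM).
#' @param fractions \code{"na_fractions"} on the same grid (typically
#'   regridded and PSF-smoothed).
#' @param csf_mM Fixed CSF concentration subtracted from the observations
#'   (default 140). Use \code{csf_free = TRUE} to estimate it instead.
#' @param mask_rule Function of (f_gm, f_wm, f_csf) returning a logical mask;
#'   default keeps voxels with total tissue fraction >= 0.5.
#' @param csf_free Estimate CSF as a third unknown (sensitivity analysis).
#' @return Object of class \code{"na_atsc"}: \code{atsc_gm}, \code{atsc_wm}
#'   (mM), \code{atsc_csf} (NA unless \code{csf_free}), \code{n_voxels_used},
#'   \code{residual_rms} (mM), \code{design_condition_number}.
#' @export
solve_global_atsc <- function(image, fractions, csf_mM = 140,
                              mask_rule = NULL, csf_free = FALSE) {
  stopifnot(inherits(fractions, "na_fractions"))
  obs <- if (is.list(image)) image$data else image
  if (!identical(dim(obs), dim(fractions$f_gm)))
    stop("image and fractions must share one grid; regrid the fractions first")
  if (is.null(mask_rule))
    mask_rule <- function(f_gm, f_wm, f_csf) f_gm + f_wm + f_csf >= 0.5
  mask <- mask_rule(fractions$f_gm, fractions$f_wm, fractions$f_csf)
  if (!any(mask)) stop("no voxels pass the mask rule")
  fg <- fractions$f_gm[mask]; fw <- fractions$f_wm[mask]
  fc <- fractions$f_csf[mask]; y <- obs[mask]
  if (length(y) < 2L) stop("need at least 2 voxels for the regression")

  X <- if (csf_free) cbind(gm = fg, wm = fw, csf = fc) else cbind(gm = fg, wm = fw)
  if (!csf_free) y <- y - fc * csf_mM
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > 1e8)
    stop(sprintf(paste("rank-deficient design (condition number %.3g):",
                       "tissue fractions do not separate GM from WM"), cond))
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  structure(list(atsc_gm = unname(beta["gm"]), atsc_wm = unname(beta["wm"]),
                 atsc_csf = if (csf_free) unname(beta["csf"]) else NA_real_,
                 n_voxels_used = length(y),
                 residual_rms = sqrt(mean(fit$residuals^2)),
                 design_condition_number = cond),
            class = "na_atsc")
}

#' @export
print.na_atsc <- function(x, ...) {
  cat(sprintf("Global aTSC: GM %.3f mM, WM %.3f mM%s\n", x$atsc_gm, x$atsc_wm,
              if (is.finite(x$atsc_csf)) sprintf(", CSF %.3f mM", x$atsc_csf) else ""))
  cat(sprintf("  %d voxels, residual RMS %.3f mM, condition number %.3g\n",
              x$n_voxels_used, x$residual_rms, x$design_condition_number))
  invisible(x)
}

#' Full quantification of one simulated or real sodium volume
#'
#' Chains the standard pipeline: regrid the high-resolution tissue fractions
#' to the sodium grid, smooth them with the acquisition PSF, calibrate the
#' raw volume against its background-noise and eye references (with PSF
#' retention correction of the eye reference by default), and solve the
#' partial-volume regression.
#'
#' @param raw An \code{"na_raw"} volume.
#' @param fractions High-resolution \code{"na_fractions"}.
#' @param f_eye Optional high-resolution eye fraction map enabling the
#'   reference retention correction.
#' @param csf_mM CSF concentration for the regression (default 140).
#' @param kernel_size Odd extent of the sodium-resolution PSF kernel.
#' @param mask_rule Passed to \code{\link{solve_global_atsc}}.
#' @return An \code{"na_atsc"} estimate with the calibration model attached
#'   as attribute \code{"calibration"}.
#' @export
quantify_volume <- function(raw, fractions, f_eye = NULL, csf_mM = 140,
                            kernel_size = 11L, mask_rule = NULL) {
  truth <- raw$truth
  lo_vox <- truth$lo_res_voxel_mm
  klo <- build_psf_kernel(truth$t2_ms, truth$readout_ms, voxel_mm = lo_vox,
                          size = kernel_size)
  frac_lo <- regrid_fractions(fractions, lo_vox)
  frac_sm <- smooth_fractions(frac_lo, klo)
  retention <- NULL
  if (!is.null(f_eye)) {
    src_vox <- diag(fractions$affine)[1:3]
    ratio <- as.integer(round(lo_vox / src_vox))
    if (identical(dim(f_eye), dim(fractions$f_gm)) && any(ratio > 1L)) {
      ## eye mask at segmentation resolution: predict retention with the
      ## acquisition-resolution forward model (blur at hi-res, then regrid)
      khi <- build_psf_kernel(truth$t2_ms, truth$readout_ms, voxel_mm = src_vox,
                              nominal_mm = max(lo_vox))
      blurred <- block_average(convolve3d(f_eye, khi), ratio)
      idx <- do.call(rbind, raw$eye_regions)
      retention <- mean(blurred[region_linear(idx, dim(blurred))])
    } else {
      retention <- psf_retention(f_eye, klo, do.call(rbind, raw$eye_regions))
    }
  }
  img <- calibrate_volume(raw, retention = retention, clamp_negative = FALSE)
  est <- solve_global_atsc(img, frac_sm, csf_mM = csf_mM, mask_rule = mask_rule)
  attr(est, "calibration") <- img$calibration
  est
}

#' Normalized ventricular volume
#'
#' Sum of the bilateral ventricular volumes divided by the estimated total
#' intracranial volume, a dimensionless index that controls for head size.
#'
#' @param left_mm3,right_mm3 Ventricular volumes (same units), >= 0.
#' @param etiv_mm3 Estimated total intracranial volume, > 0.
#' @return Dimensionless ratio.
#' @examples
#' normalized_ventricular_volume(5000, 5000, 1e6)  # 0.01
#' @export
normalized_ventricular_volume <- function(left_mm3, right_mm3, etiv_mm3) {
  if (any(!is.finite(c(left_mm3, right_mm3, etiv_mm3))))
    stop("volumes must be finite")
  if (any(left_mm3 < 0) || any(right_mm3 < 0)) stop("ventricular volumes must be >= 0")
  if (any(etiv_mm3 <= 0)) stop("etiv_mm3 must be positive")
  (left_mm3 + right_mm3) / etiv_mm3
}
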