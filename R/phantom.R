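#' Ground-truth parameters for a synthetic sodium phantom
#'
#' Bundles the tissue sodium concentrations, grid resolutions, PSF and noise
#' parameters that define one simulated acquisition. CSF and vitreous humour
#' default to 140 mM, the concentration assumed for the internal reference;
#' the PSF defaults to mono-exponential T2 decay with T2 = 56 ms over a
#' 36.3 ms readout at a 6 mm nominal sodium resolution.
#'
#' @param c_gm,c_wm,c_csf,c_eye Tissue concentrations (mM), all non-negative.
#' @param hi_res_voxel_mm High-resolution (segmentation) voxel size, length 3
#'   or scalar.
#' @param lo_res_voxel_mm Sodium voxel size; must be componentwise at least
#'   the high resolution.
#' @param t2_ms Transverse relaxation time driving the PSF (ms).
#' @param readout_ms Effective readout duration (ms).
#' @param noise_sigma Noise standard deviation in raw signal units.
#' @param noise_model \code{"rician"} (magnitude image, default) or
#'   \code{"gaussian"}.
#' @param gain Fixed signal gain, raw units per mM.
#' @param seed RNG seed used by \code{\link{simulate_acquisition}}.
#' @return Object of class \code{"na_truth"}.
#' @export
phantom_truth <- function(c_gm = 35, c_wm = 30, c_csf = 140, c_eye = 140,
                          hi_res_voxel_mm = c(2, 2, 2),
                          lo_res_voxel_mm = c(6, 6, 6),
                          t2_ms = 56, readout_ms = 36.3,
                          noise_sigma = 0, noise_model = c("rician", "gaussian"),
                          gain = 10, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (length(hi_res_voxel_mm) == 1L) hi_res_voxel_mm <- rep(hi_res_voxel_mm, 3L)
  if (length(lo_res_voxel_mm) == 1L) lo_res_voxel_mm <- rep(lo_res_voxel_mm, 3L)
  conc <- c(c_gm = c_gm, c_wm = c_wm, c_csf = c_csf, c_eye = c_eye)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("all concentrations must be finite and >= 0")
  if (any(hi_res_voxel_mm <= 0) || any(lo_res_voxel_mm <= 0))
    stop("voxel sizes must be positive")
  if (any(lo_res_voxel_mm < hi_res_voxel_mm - 1e-12))
    stop("lo_res_voxel_mm must be >= hi_res_voxel_mm componentwise")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("noise_sigma must be >= 0")
  stop_if_not_scalar_pos(t2_ms, "t2_ms")
  stop_if_not_scalar_pos(readout_ms, "readout_ms")
  stop_if_not_scalar_pos(gain, "gain")
  structure(list(c_gm = c_gm, c_wm = c_wm, c_csf = c_csf, c_eye = c_eye,
                 hi_res_voxel_mm = hi_res_voxel_mm,
                 lo_res_voxel_mm = lo_res_voxel_mm,
                 t2_ms = t2_ms, readout_ms = readout_ms,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 gain = gain, seed = as.integer(seed)),
            class = "na_truth")
}

#' Geometry of the ellipsoidal head phantom
#'
#' Nested ellipsoids model (outermost to innermost) a subarachnoid CSF rim, a
#' cortical grey-matter shell and a white-matter core containing two
#' ellipsoidal lateral ventricles; two spheres anterior to the brain model the
#' eyes (vitreous humour). All dimensions in mm, world coordinates centred on
#' the volume.
#'
#' @param grid_shape High-resolution grid dimensions (length 3 or scalar).
#' @param brain_center Centre of the brain ellipsoids.
#' @param csf_semi,gm_semi,wm_semi Semi-axes of the CSF rim, GM and WM
#'   ellipsoids (outer surfaces).
#' @param vent_semi Semi-axes of each lateral ventricle.
#' @param vent_offset Offset of the right ventricle centre from the brain
#'   centre (left is mirrored in x).
#' @param eye_center Centre of the right eye (left mirrored in x).
#' @param eye_radius_mm Eye radius.
#' @param eye_erosion_mm Margin eroded from the eye surface when declaring
#'   reference voxels, keeping them clear of PSF edge spill.
#' @param supersample Sub-voxel sampling factor per axis used to turn the
#'   analytic geometry into partial-volume fractions.
#' @return Object of class \code{"na_geometry"}.
#' @export
phantom_geometry <- function(grid_shape = c(84, 84, 84),
                             brain_center = c(0, 8, 0),
                             csf_semi = c(48, 40, 40),
                             gm_semi = c(44, 36, 36),
                             wm_semi = c(36, 28, 28),
                             vent_semi = c(15, 8, 8),
                             vent_offset = c(10, 4, 4),
                             eye_center = c(21, -57, -3),
                             eye_radius_mm = 13,
                             eye_erosion_mm = 5.5,
                             supersample = 2L) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  stopifnot(all(grid_shape >= 4), eye_radius_mm > 0, supersample >= 1)
  g <- structure(list(grid_shape = as.integer(grid_shape),
                      brain_center = brain_center, csf_semi = csf_semi,
                      gm_semi = gm_semi, wm_semi = wm_semi,
                      vent_semi = vent_semi, vent_offset = vent_offset,
                      eye_center = eye_center, eye_radius_mm = eye_radius_mm,
                      eye_erosion_mm = eye_erosion_mm,
                      supersample = as.integer(supersample)),
                 class = "na_geometry")
  if (!all(gm_semi < csf_semi) || !all(wm_semi < gm_semi))
    stop("ellipsoids must nest: wm_semi < gm_semi < csf_semi")
  ## eye must sit clear of the outer CSF surface (conservative radial bound)
  d <- sqrt(sum(((eye_center - brain_center) / csf_semi)^2))
  if ((d - 1) * min(csf_semi) <= eye_radius_mm)
    stop("eye overlaps the brain: move eye_center or shrink eye_radius_mm")
  g
}

#' Smaller phantom geometry for quick demonstrations
#'
#' A scaled-down head on a 48-voxel grid, used by the demo pipeline and in
#' examples where full-size simulation would be unnecessarily slow.
#' @return Object of class \code{"na_geometry"}.
#' @export
phantom_geometry_demo <- function() {
  phantom_geometry(grid_shape = c(48, 48, 48),
                   brain_center = c(0, 4, 0),
                   csf_semi = c(24, 20, 20), gm_semi = c(21, 17, 17),
                   wm_semi = c(17, 13, 13),
                   vent_semi = c(7, 4, 4), vent_offset = c(6, 2, 2),
                   eye_center = c(9, -33, 3), eye_radius_mm = 9,
                   eye_erosion_mm = 5.5)
}

#' Generate tissue-fraction maps and the ground-truth concentration field
#'
#' Rasterizes the ellipsoidal geometry into per-voxel GM/WM/CSF volume
#' fractions (via sub-voxel supersampling, so boundary voxels carry partial
#' fractions) plus an eye fraction, and forms the noiseless concentration
#' field \code{f_gm*c_gm + f_wm*c_wm + f_csf*c_csf + f_eye*c_eye} with zero
#' background. Deterministic given its arguments.
#'
#' @param geometry An \code{\link{phantom_geometry}} object.
#' @param truth An \code{\link{phantom_truth}} object.
#' @return Object of class \code{"na_phantom"}: fields \code{fractions} (class
#'   \code{"na_fractions"}: arrays \code{f_gm}, \code{f_wm}, \code{f_csf},
#'   affine, grid shape), \code{f_eye}, \code{concentration}, \code{affine},
#'   \code{truth}, \code{geometry}.
#' @export
generate_phantom <- function(geometry = phantom_geometry(),
                             truth = phantom_truth()) {
  stopifnot(inherits(geometry, "na_geometry"), inherits(truth, "na_truth"))
  gs <- geometry$grid_shape
  vox <- truth$hi_res_voxel_mm
  affine <- centered_affine(vox, gs)
  ss <- geometry$supersample
  n_sub <- ss^3

  counts <- list(gm = 0, wm = 0, csf = 0, eye = 0)
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss   # sub-voxel offsets in voxel units
  co <- axis_coords(affine, gs)
  for (ox in offs) for (oy in offs) for (oz in offs) {
    lab <- classify_points(co[[1]] + ox * vox[1], co[[2]] + oy * vox[2],
                           co[[3]] + oz * vox[3], geometry)
    counts$gm <- counts$gm + lab$gm
    counts$wm <- counts$wm + lab$wm
    counts$csf <- counts$csf + lab$csf
    counts$eye <- counts$eye + lab$eye
  }
  f_gm <- counts$gm / n_sub; f_wm <- counts$wm / n_sub
  f_csf <- counts$csf / n_sub; f_eye <- counts$eye / n_sub

  fractions <- new_fractions(f_gm, f_wm, f_csf, affine)
  conc <- f_gm * truth$c_gm + f_wm * truth$c_wm + f_csf * truth$c_csf +
    f_eye * truth$c_eye
  structure(list(fractions = fractions, f_eye = f_eye,
                 concentration = conc, affine = affine, truth = truth,
                 geometry = geometry),
            class = "na_phantom")
}

## label supersampled points; returns 0/1 arrays per class over the full grid
classify_points <- function(x, y, z, geom) {
  ca <- coord_arrays(x, y, z)
  X <- ca$X; Y <- ca$Y; Z <- ca$Z
  ell <- function(center, semi)
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
  bc <- geom$brain_center
  in_csf_out <- ell(bc, geom$csf_semi)
  in_gm_out <- ell(bc, geom$gm_semi)
  in_wm <- ell(bc, geom$wm_semi)
  vr <- geom$vent_offset
  in_vent <- ell(bc + vr, geom$vent_semi) | ell(bc + vr * c(-1, 1, 1), geom$vent_semi)
  ec <- geom$eye_center
  dist_r <- sqrt((X - ec[1])^2 + (Y - ec[2])^2 + (Z - ec[3])^2)
  dist_l <- sqrt((X + ec[1])^2 + (Y - ec[2])^2 + (Z - ec[3])^2)
  in_eye <- dist_r <= geom$eye_radius_mm | dist_l <= geom$eye_radius_mm
  csf <- (in_csf_out & !in_gm_out) | (in_wm & in_vent)
  gm <- in_gm_out & !in_wm
  wm <- in_wm & !in_vent
  list(gm = gm + 0, wm = wm + 0, csf = csf + 0, eye = in_eye + 0)
}

#' Construct a tissue-fraction map triple
#'
#' @param f_gm,f_wm,f_csf 3-D arrays of per-voxel volume fractions sharing one
#'   grid; each in \[0,1\] and summing to at most 1 per voxel.
#' @param affine 4x4 grid-to-world matrix.
#' @return Object of class \code{"na_fractions"}.
#' @export
new_fractions <- function(f_gm, f_wm, f_csf, affine) {
  stopifnot(identical(dim(f_gm), dim(f_wm)), identical(dim(f_gm), dim(f_csf)),
            length(dim(f_gm)) == 3L, identical(dim(affine), c(4L, 4L)))
  rng <- range(f_gm, f_wm, f_csf)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("tissue fractions must lie in [0, 1]")
  if (max(f_gm + f_wm + f_csf) > 1 + 1e-9)
    stop("tissue fractions must sum to at most 1 per voxel")
  structure(list(f_gm = f_gm, f_wm = f_wm, f_csf = f_csf, affine = affine,
                 grid_shape = dim(f_gm)),
            class = "na_fractions")
}

#' @export
print.na_phantom <- function(x, ...) {
  cat("Sodium head phantom\n")
  cat(sprintf("  hi-res grid: %s at %s mm\n",
              paste(x$fractions$grid_shape, collapse = "x"),
              paste(x$truth$hi_res_voxel_mm, collapse = "x")))
  cat(sprintf("  truth (mM): GM %.4g, WM %.4g, CSF %.4g, eye %.4g\n",
              x$truth$c_gm, x$truth$c_wm, x$truth$c_csf, x$truth$c_eye))
  invisible(x)
}
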