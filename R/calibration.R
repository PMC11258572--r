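#' Estimate the background noise level of a raw sodium volume
#'
#' Sample standard deviation (denominator n-1) of the raw signal over the
#' recorded background region (560 voxels from the corner of the central
#' slice, by default, in simulated volumes).
#'
#' @param volume An \code{"na_raw"} volume from
#'   \code{\link{simulate_acquisition}}, or any list with a \code{signal}
#'   array and a \code{background_region} index matrix.
#' @return Noise SD in raw signal units.
#' @examples
#' v <- list(signal = array(c(1, 2, 3, 4), c(4, 1, 1)),
#'           background_region = cbind(1:4, 1L, 1L))
#' estimate_noise_sd(v)  # sd of 1:4 = 1.290994
#' @export
estimate_noise_sd <- function(volume) {
  bg <- volume$background_region
  if (is.null(bg) || nrow(bg) < 2L)
    stop("background region must contain at least 2 voxels")
  stats::sd(volume$signal[region_linear(bg, dim(volume$signal))])
}

#' Mean raw signal over the eye (vitreous humour) reference regions
#'
#' Pools both eyes' reference voxels. When \code{retention} is supplied, the
#' pooled mean is divided by it to undo the fraction of vitreous signal the
#' point-spread function moves out of the reference voxels (see
#' \code{\link{psf_retention}}); without it the raw ROI mean is returned.
#'
#' @param volume An \code{"na_raw"} volume with an \code{eye_regions} list.
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @param retention Optional scalar in (0, 1\]: predicted PSF retention of the
#'   reference voxels.
#' @return Reference signal in raw units.
#' @export
eye_reference_signal <- function(volume, statistic = c("mean", "median"),
                                 retention = NULL) {
  statistic <- match.arg(statistic)
  idx <- do.call(rbind, volume$eye_regions)
  if (is.null(idx) || nrow(idx) == 0) stop("no eye reference voxels recorded")
  vals <- volume$signal[region_linear(idx, dim(volume$signal))]
  out <- if (statistic == "mean") mean(vals) else stats::median(vals)
  if (!is.null(retention)) {
    if (!is.numeric(retention) || retention <= 0 || retention > 1)
      stop("'retention' must be in (0, 1]")
    out <- out / retention
  }
  out
}

#' Predicted PSF retention of a reference region
#'
#' Fraction of a region's ideal signal that remains in given voxels after PSF
#' blurring: the region's indicator (or fraction) map is convolved with the
#' kernel and read at the reference voxels.
#'
#' @param f_region Region fraction map (3-D array, 1 inside the region).
#' @param kernel Normalized PSF kernel on the same grid.
#' @param voxels n x 3 voxel-index matrix of the reference voxels.
#' @return Mean predicted retention over the voxels.
#' @export
psf_retention <- function(f_region, kernel, voxels) {
  if (abs(sum(kernel) - 1) > 1e-6) stop("kernel must be normalized")
  blurred <- convolve3d(f_region, kernel)
  mean(blurred[region_linear(voxels, dim(f_region))])
}

#' Fit the two-anchor internal-reference calibration
#'
#' Unique line through the anchors (noise_sd, 0 mM) and (eye_mean, 140 mM):
#' the background noise level maps to 0 mM and the vitreous humour reference
#' to the assumed 140 mM, so \code{slope = 140 / (eye_mean - noise_sd)} and
#' \code{intercept = -slope * noise_sd}.
#'
#' @param noise_sd Background noise SD (raw units).
#' @param eye_mean Eye reference signal (raw units); must exceed
#'   \code{noise_sd}.
#' @param reference_mM Reference concentration (default 140 mM).
#' @return Object of class \code{"na_calibration"} with fields \code{slope}
#'   (mM per raw unit), \code{intercept} (mM), \code{noise_sd},
#'   \code{eye_mean}, \code{reference_mM}.
#' @examples
#' m <- fit_calibration(noise_sd = 2, eye_mean = 72)
#' m$slope * 37 + m$intercept  # 70 mM, halfway between the anchors
#' @export
fit_calibration <- function(noise_sd, eye_mean, reference_mM = 140) {
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.numeric(eye_mean) || eye_mean <= noise_sd)
    stop("eye reference signal must exceed the noise level; reference unusable")
  slope <- reference_mM / (eye_mean - noise_sd)
  structure(list(slope = slope, intercept = -slope * noise_sd,
                 noise_sd = noise_sd, eye_mean = eye_mean,
                 reference_mM = reference_mM),
            class = "na_calibration")
}

#' Apply a calibration model to a raw volume
#'
#' Voxelwise affine map from raw signal to concentration (mM). Negative
#' calibrated values are floored at 0 by default; keep them (for unbiased
#' regression residuals) with \code{clamp_negative = FALSE}.
#'
#' @param volume An \code{"na_raw"} volume.
#' @param model An \code{"na_calibration"} model.
#' @param clamp_negative Floor negative concentrations at 0 (default TRUE).
#' @return Object of class \code{"na_image"}: \code{data} (mM array),
#'   \code{affine}, \code{calibration}, plus the volume's reference regions.
#' @export
apply_calibration <- function(volume, model, clamp_negative = TRUE) {
  stopifnot(inherits(model, "na_calibration"))
  conc <- model$slope * volume$signal + model$intercept
  if (clamp_negative) conc[conc < 0] <- 0
  structure(list(data = conc, affine = volume$affine, calibration = model,
                 background_region = volume$background_region,
                 eye_regions = volume$eye_regions),
            class = "na_image")
}

#' Calibrate a raw sodium volume in one step
#'
#' Convenience wrapper: estimates the background noise SD, extracts the eye
#' reference signal (optionally retention-corrected), fits the two-anchor
#' model and applies it.
#'
#' @inheritParams apply_calibration
#' @inheritParams eye_reference_signal
#' @return An \code{"na_image"} concentration volume.
#' @export
calibrate_volume <- function(volume, retention = NULL, clamp_negative = TRUE,
                             statistic = "mean") {
  noise_sd <- estimate_noise_sd(volume)
  eye_mean <- eye_reference_signal(volume, statistic = statistic,
                                   retention = retention)
  apply_calibration(volume, fit_calibration(noise_sd, eye_mean),
                    clamp_negative = clamp_negative)
}

#' @export
print.na_calibration <- function(x, ...) {
  cat(sprintf("Sodium calibration: %.6g mM/unit x signal %+.6g mM\n",
              x$slope, x$intercept))
  cat(sprintf("  anchors: noise SD %.6g -> 0 mM; eye %.6g -> %g mM\n",
              x$noise_sd, x$eye_mean, x$reference_mM))
  invisible(x)
}
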