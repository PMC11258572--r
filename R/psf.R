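#' Build the sodium point-spread-function kernel
#'
#' Constructs the image-space blurring kernel implied by mono-exponential T2
#' signal decay during a centre-out readout. In k-space the acquired signal is
#' weighted by \code{exp(-t(k)/T2)}, where the acquisition time \code{t(k)}
#' grows linearly with \code{|k|} from 0 at the k-space centre to
#' \code{readout_ms} at the band edge \code{k_max}. \code{k_max} is the
#' Nyquist frequency of the acquisition's nominal resolution
#' (\code{nominal_mm}); the acquisition time is capped at \code{readout_ms}
#' for any grid frequency beyond it. The kernel is the inverse Fourier
#' transform of this radially
#' symmetric weighting, sampled on a grid of spacing \code{voxel_mm}, so the
#' same continuous PSF can be discretized at the simulation (high) and sodium
#' (low) resolutions.
#'
#' @param t2_ms Transverse relaxation time in ms; must be positive (may be
#'   \code{Inf} for a decay-free kernel).
#' @param readout_ms Effective readout duration in ms (time to traverse from
#'   k-space centre to \code{k_max}).
#' @param voxel_mm Grid spacing (mm) on which the kernel is sampled; scalar or
#'   length-3.
#' @param kernel_mode \code{"exponential_kspace"} (default) or
#'   \code{"gaussian"}, the latter an isotropic Gaussian whose FWHM matches the
#'   exponential kernel's main lobe.
#' @param nominal_mm Nominal acquisition resolution (mm) defining
#'   \code{k_max = 1/(2 nominal_mm)}; defaults to \code{max(voxel_mm)} (kernel
#'   grid at acquisition resolution).
#' @param size Odd kernel extent per axis (voxels); default covers ~30 mm
#'   half-width.
#' @return 3-D array summing to 1, with attributes \code{voxel_mm},
#'   \code{fwhm_mm} and \code{mode}.
#' @examples
#' k <- build_psf_kernel(56, 36.3, voxel_mm = 6)
#' sum(k)           # 1
#' attr(k, "fwhm_mm")
#' @export
build_psf_kernel <- function(t2_ms, readout_ms, voxel_mm,
                             kernel_mode = c("exponential_kspace", "gaussian"),
                             nominal_mm = NULL, size = NULL) {
  kernel_mode <- match.arg(kernel_mode)
  if (!is.numeric(t2_ms) || length(t2_ms) != 1L || is.na(t2_ms) || t2_ms <= 0)
    stop("'t2_ms' must be a single positive number")
  stop_if_not_scalar_pos(readout_ms, "readout_ms")
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  stopifnot(length(voxel_mm) == 3L, all(voxel_mm > 0))
  if (is.null(nominal_mm)) nominal_mm <- max(voxel_mm)
  stop_if_not_scalar_pos(nominal_mm, "nominal_mm")
  if (is.null(size)) size <- 2L * ceiling(30 / voxel_mm) + 1L
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  if (any(size < 1L) || any(size %% 2L == 0L))
    stop("'size' must be odd and positive per axis")

  kern <- psf_exponential(t2_ms, readout_ms, voxel_mm, nominal_mm, size)
  fwhm <- kernel_fwhm_mm(kern, voxel_mm)
  if (kernel_mode == "gaussian") {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    ax <- lapply(1:3, function(a) {
      x <- (seq_len(size[a]) - (size[a] + 1) / 2) * voxel_mm[a]
      if (sigma <= .Machine$double.eps) as.numeric(x == 0) else exp(-x^2 / (2 * sigma^2))
    })
    kern <- outer(outer(ax[[1]], ax[[2]]), ax[[3]])
    dim(kern) <- size
    fwhm <- kernel_fwhm_mm(kern, voxel_mm)
  }
  kern <- kern / sum(kern)
  structure(kern, voxel_mm = voxel_mm, fwhm_mm = fwhm, mode = kernel_mode)
}

## inverse DFT of the band-limited exponential k-space weighting
psf_exponential <- function(t2_ms, readout_ms, voxel_mm, nominal_mm, size) {
  k_max <- 1 / (2 * nominal_mm)
  freqs <- lapply(1:3, function(a) fft_freqs(size[a], voxel_mm[a]))
  kk <- coord_arrays(freqs[[1]], freqs[[2]], freqs[[3]])
  kr <- sqrt(kk$X^2 + kk$Y^2 + kk$Z^2)
  ## t(k) grows linearly to readout_ms at k_max and is capped there, so the
  ## weighting is exp(-readout/T2) for any grid frequency beyond the nominal
  ## band edge; with T2 -> Inf the weights are all 1 and the kernel is a delta.
  w <- exp(-(readout_ms * pmin(kr, k_max) / k_max) / t2_ms)
  kern <- Re(stats::fft(w, inverse = TRUE)) / prod(size)
  kern <- fft_shift3(kern)
  kern / sum(kern)
}

## DFT sample frequencies (cycles/mm) in standard fft ordering
fft_freqs <- function(n, d) {
  i <- 0:(n - 1)
  i[i > n %/% 2] <- i[i > n %/% 2] - n
  i / (n * d)
}

## move the DC sample to the array centre (odd sizes)
fft_shift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    h <- n %/% 2
    c((n - h + 1):n, 1:(n - h))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Full width at half maximum of a kernel's central profile
#'
#' Measures the main-lobe FWHM (mm) along the first axis through the kernel
#' centre, with linear interpolation at the half-maximum crossings.
#'
#' @param kern 3-D kernel array (odd dimensions).
#' @param voxel_mm Grid spacing; scalar or length-3.
#' @return FWHM in mm (0 for a discrete delta).
#' @export
kernel_fwhm_mm <- function(kern, voxel_mm = attr(kern, "voxel_mm")) {
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  d <- dim(kern)
  c2 <- (d[2] + 1) %/% 2; c3 <- (d[3] + 1) %/% 2
  prof <- kern[, c2, c3]
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * voxel_mm[1]
  pk <- which.max(prof)
  half <- prof[pk] / 2
  right <- pk
  while (right < length(prof) && prof[right + 1] >= half) right <- right + 1
  if (right == length(prof)) return(abs(2 * (x[right] - x[pk])))
  x_r <- x[right] + (half - prof[right]) / (prof[right + 1] - prof[right]) *
    (x[right + 1] - x[right])
  left <- pk
  while (left > 1 && prof[left - 1] >= half) left <- left - 1
  if (left == 1) return(x_r - x[pk] + (x[pk] - x[left]))
  x_l <- x[left] + (half - prof[left]) / (prof[left - 1] - prof[left]) *
    (x[left - 1] - x[left])
  x_r - x_l
}

#' Delta (identity) kernel
#'
#' @param size Odd extent per axis.
#' @return 3-D array with a single central 1.
#' @export
delta_kernel <- function(size = 1L) {
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  stopifnot(all(size %% 2L == 1L))
  k <- array(0, size)
  k[(size[1] + 1) %/% 2, (size[2] + 1) %/% 2, (size[3] + 1) %/% 2] <- 1
  k
}

#' Convolve a 3-D volume with a kernel using edge-replicating padding
#'
#' FFT-based linear convolution; the volume is padded by replicating its edge
#' values so that a normalized kernel maps a constant field to itself.
#'
#' @param x 3-D array.
#' @param kern 3-D kernel, odd dimensions, no larger than \code{x} per axis.
#' @return Array of the same shape as \code{x}.
#' @export
convolve3d <- function(x, kern) {
  stopifnot(length(dim(x)) == 3L, length(dim(kern)) == 3L)
  kd <- dim(kern)
  if (any(kd %% 2L == 0L)) stop("kernel dimensions must be odd")
  half <- kd %/% 2L
  if (all(half == 0L)) return(x * as.numeric(kern))
  xd <- dim(x)
  pidx <- lapply(1:3, function(a) {
    i <- c(rep(1L, half[a]), seq_len(xd[a]), rep(xd[a], half[a]))
    i
  })
  xp <- x[pidx[[1]], pidx[[2]], pidx[[3]], drop = FALSE]
  pd <- dim(xp)
  kp <- array(0, pd)
  kp[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kern
  ## circular shift so the kernel centre sits at index (1,1,1)
  sidx <- lapply(1:3, function(a) {
    n <- pd[a]
    ((seq_len(n) - 1L + half[a]) %% n) + 1L
  })
  kp <- kp[sidx[[1]], sidx[[2]], sidx[[3]], drop = FALSE]
  out <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) / prod(pd)
  out[half[1] + seq_len(xd[1]), half[2] + seq_len(xd[2]), half[3] + seq_len(xd[3]),
      drop = FALSE]
}
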