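#' Evaluate an expression under a fixed RNG seed
#'
#' Runs \code{expr} with the global RNG seeded at \code{seed} and restores the
#' caller's RNG state afterwards, so seeded simulation helpers do not perturb
#' the session stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Simple diagonal affine: voxel indices (1-based) -> world mm, volume centred
## on the world origin.
centered_affine <- function(voxel_mm, grid_shape) {
  stopifnot(length(voxel_mm) == 3L, length(grid_shape) == 3L, all(voxel_mm > 0))
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_mm)
  ## voxel i has world coordinate (i - (n+1)/2) * d
  A[1:3, 4] <- -voxel_mm * (grid_shape + 1) / 2
  A
}

## World coordinates (mm) of voxel centres along each axis.
axis_coords <- function(affine, grid_shape) {
  lapply(1:3, function(ax) affine[ax, ax] * seq_len(grid_shape[ax]) + affine[ax, 4])
}

## Expand per-axis coordinate vectors into three full 3-D arrays.
coord_arrays <- function(x, y, z) {
  gs <- c(length(x), length(y), length(z))
  list(X = array(x, gs),
       Y = array(rep(y, each = gs[1]), gs),
       Z = array(rep(z, each = gs[1] * gs[2]), gs))
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
}

## Convert an n x 3 integer voxel-index matrix to linear indices into an array.
region_linear <- function(idx, dim3) {
  stopifnot(ncol(idx) == 3L)
  (idx[, 3] - 1L) * dim3[1] * dim3[2] + (idx[, 2] - 1L) * dim3[1] + idx[, 1]
}
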