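## Independent brute-force oracles for the exact permutation tests. These
## literally materialize every labeling / sign pattern / permutation and are
## deliberately written without reference to the package internals.

oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  labelings <- utils::combn(n1 + n2, n1)
  us <- apply(labelings, 2, u_stat)
  lower <- mean(us <= u_obs + 1e-9)
  upper <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

oracle_wsrt_p <- function(diffs) {
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  r <- rank(abs(diffs))
  w_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

## all permutations via repeated index shuffling of a recursion-free scheme
oracle_perm_matrix <- function(n) {
  if (requireNamespace("e1071", quietly = TRUE)) return(e1071::permutations(n))
  if (n == 1) return(matrix(1, 1, 1))
  sub <- oracle_perm_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, matrix(seq_len(n)[-k][sub], nrow(sub), n - 1))))
}

oracle_spearman_p <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- oracle_perm_matrix(length(y))
  rhos <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

## volume-centred diagonal affine (mirrors the package's grid convention)
centered_affine_for_test <- function(voxel_mm, grid_shape) {
  A <- diag(4)
  A[1:3, 1:3] <- diag(voxel_mm)
  A[1:3, 4] <- -voxel_mm * (grid_shape + 1) / 2
  A
}

## small deterministic fixtures reused across tests
demo_phantom <- local({
  cache <- NULL
  function(truth = phantom_truth()) {
    if (is.null(cache) || !identical(attr(cache, "truth_key"), truth)) {
      ph <- generate_phantom(phantom_geometry_demo(), truth)
      attr(ph, "truth_key") <- truth
      cache <<- ph
    }
    cache
  }
})
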