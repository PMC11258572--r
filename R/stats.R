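## Nonparametric inference toolkit: Mann-Whitney U, matched-pair Wilcoxon
## signed-rank and Spearman correlation with exact permutation p-values for
## small samples, plus Cohen's d. Exact tail counts are obtained from the
## rank-sum generating function, which enumerates the same label/sign
## assignments as brute force without materializing them; midrank ties are
## handled exactly by doubling the (half-integer) midranks to integers.

new_stat_result <- function(statistic, p_value, method, effect_size = NULL, ...) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(c(list(statistic = statistic, p_value = min(p_value, 1),
                   method = method, effect_size = effect_size), list(...)),
            class = "na_stat")
}

#' @export
print.na_stat <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g", x$method, x$statistic, x$p_value))
  if (!is.null(x$effect_size)) cat(sprintf(", effect size = %.4g", x$effect_size))
  cat("\n")
  invisible(x)
}

## distribution of the subset rank-sum: number of n1-subsets of `ranks2`
## (midranks doubled to integers) attaining each sum; column k of the DP
## table holds counts for subsets of size k
subset_sum_counts <- function(ranks2, n1) {
  total <- sum(ranks2)
  counts <- matrix(0, nrow = total + 1L, ncol = n1 + 1L)
  counts[1L, 1L] <- 1
  for (r in ranks2) {
    for (k in n1:1L) {   # iterate sizes downward (0/1 knapsack)
      nz <- which(counts[, k] > 0)
      if (length(nz)) counts[nz + r, k + 1L] <- counts[nz + r, k + 1L] + counts[nz, k]
    }
  }
  counts[, n1 + 1L]
}

## distribution of the positive-part signed-rank sum over all 2^n sign
## patterns (midranks doubled to integers)
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    nz <- which(counts > 0)
    shifted <- numeric(total + 1L)
    shifted[nz + r] <- counts[nz]
    counts <- counts + shifted
  }
  counts
}

## two-sided p from an exact discrete distribution: double the smaller tail
## (observed value included), capped at 1
two_sided_tail <- function(counts, obs_index) {
  total <- sum(counts)
  lower <- sum(counts[seq_len(obs_index)])
  upper <- sum(counts[obs_index:length(counts)])
  min(1, 2 * min(lower, upper) / total)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie handling.
#' The p-value is exact (full enumeration of the \eqn{C(n_1+n_2, n_1)} group
#' labelings via the rank-sum generating function) when \eqn{n_1+n_2 \le 20}
#' and the data are tie-free; otherwise a normal approximation with tie and
#' continuity corrections is used. \code{exact = "always"} forces the exact
#' permutation distribution of the observed midranks even with ties.
#'
#' @param x,y Numeric samples (first argument conventionally the patients).
#' @param exact \code{"auto"} (default), \code{"always"} or \code{"never"}.
#' @return \code{"na_stat"} with the U statistic of \code{x}, two-sided
#'   p-value, sample sizes \code{n1}, \code{n2} and the method label.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # 1/3 by full enumeration
#' @export
mann_whitney_u <- function(x, y, exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  ranks <- rank(c(x, y))
  r1 <- sum(ranks[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- switch(exact,
                      auto = (n1 + n2 <= 20L) && !ties,
                      always = TRUE, never = FALSE)
  if (use_exact) {
    ranks2 <- as.integer(round(2 * ranks))
    counts <- subset_sum_counts(ranks2, n1)
    p <- two_sided_tail(counts, as.integer(round(2 * r1)) + 1L)
    method <- sprintf("Mann-Whitney U (exact%s)", if (ties) ", ties" else "")
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(ranks)
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) stop("all observations identical; test undefined")
    z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Mann-Whitney U (normal approximation)"
  }
  new_stat_result(statistic = u1, p_value = p, method = method, n1 = n1, n2 = n2)
}

#' Matched-pair Wilcoxon signed-rank test
#'
#' Tests within-subject change. Zero differences are dropped (classic
#' Wilcoxon treatment); the statistic W is the positive-rank sum of the
#' remaining differences with midrank ties. The p-value is exact (all
#' \eqn{2^n} sign patterns, via the signed-rank generating function) when
#' \eqn{n \le 20} and the |differences| are tie-free; otherwise normal
#' approximation with tie and continuity corrections. \code{exact =
#' "always"} forces the exact distribution of the observed midranks.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact \code{"auto"}, \code{"always"} or \code{"never"}.
#' @return \code{"na_stat"} with W, two-sided p, \code{n} (nonzero pairs).
#' @examples
#' wilcoxon_signed_rank(1:5)$p_value  # 2/32: all five differences positive
#' @export
wilcoxon_signed_rank <- function(diffs, exact = c("auto", "always", "never")) {
  exact <- match.arg(exact)
  diffs <- diffs[!is.na(diffs)]
  diffs <- diffs[diffs != 0]
  n <- length(diffs)
  if (n < 1L)
    stop("all differences are zero: no information for the signed-rank test")
  ranks <- rank(abs(diffs))
  w <- sum(ranks[diffs > 0])
  ties <- anyDuplicated(abs(diffs)) > 0L
  use_exact <- switch(exact, auto = n <= 20L && !ties, always = TRUE,
                      never = FALSE)
  if (use_exact) {
    ranks2 <- as.integer(round(2 * ranks))
    counts <- signed_rank_counts(ranks2)
    p <- two_sided_tail(counts, as.integer(round(2 * w)) + 1L)
    method <- sprintf("Wilcoxon signed-rank (exact%s)", if (ties) ", ties" else "")
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) stop("all |differences| identical at n too small; undefined")
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  new_stat_result(statistic = w, p_value = p, method = method, n = n)
}

#' Spearman rank correlation with permutation p-value
#'
#' Spearman's rho on midranks. For \eqn{n \le 8} the p-value is exact: the
#' proportion of all \eqn{n!} permutations of the y-ranks whose |rho| reaches
#' the observed |rho| (within 1e-12). For larger n a seeded Monte-Carlo
#' permutation p is returned, with the observed ordering counted in both
#' numerator and denominator.
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with NA dropped.
#' @param mc_draws Monte-Carlo permutations when \eqn{n > 8} (default 1e5).
#' @param seed Seed for the Monte-Carlo path.
#' @param method \code{"auto"} (exact for \eqn{n \le 8}), \code{"exact"} or
#'   \code{"montecarlo"}.
#' @return \code{"na_stat"} with rho as statistic and effect size, two-sided
#'   permutation p, \code{n}.
#' @examples
#' spearman_exact(1:5, c(2, 4, 6, 8, 10))$p_value  # 2/120
#' @export
spearman_exact <- function(x, y, mc_draws = 1e5, seed = 2025L,
                           method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L || length(y) != n) stop("need paired samples of equal length >= 3")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("rho undefined for a constant sample")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ## rho is affine in sum(rx * ry_perm) for fixed margins
  sxx <- sum((rx - mean(rx))^2); syy <- sum((ry - mean(ry))^2)
  rho_of <- function(s) (s - n * mean(rx) * mean(ry)) / sqrt(sxx * syy)
  use_exact <- switch(method, auto = n <= 8L, exact = TRUE, montecarlo = FALSE)
  if (use_exact && n > 10L) stop("exact enumeration limited to n <= 10")
  if (use_exact) {
    perms <- permutations_of(n)
    s <- apply(perms, 1L, function(pp) sum(rx * ry[pp]))
    hits <- sum(abs(rho_of(s)) >= abs(rho) - 1e-12)
    p <- hits / nrow(perms)
    method <- "Spearman rho (exact permutation)"
  } else {
    s <- with_seed(seed, vapply(seq_len(mc_draws),
                                function(i) sum(rx * ry[sample.int(n)]), 0))
    hits <- 1 + sum(abs(rho_of(s)) >= abs(rho) - 1e-12)
    p <- hits / (mc_draws + 1)
    method <- sprintf("Spearman rho (Monte-Carlo permutation, %d draws, seed %d)",
                      as.integer(mc_draws), as.integer(seed))
  }
  new_stat_result(statistic = rho, p_value = p, method = method,
                  effect_size = rho, n = n)
}

## all permutations of 1..n as an n! x n matrix (recursive construction)
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    block <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Cohen's d with pooled standard deviation
#'
#' \eqn{d = (\bar x - \bar y)/s_p} with
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}. By the package's
#' convention the first argument holds the patients and the second the
#' controls, so lower patient values give negative d.
#'
#' @param x,y Numeric samples with at least 2 non-missing values each.
#' @return Cohen's d (scalar).
#' @examples
#' cohens_d(c(0, 2), c(2, 4))  # -sqrt(2)
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group")
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("pooled SD is zero; d undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}
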