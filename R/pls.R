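#' Two-block partial least squares
#'
#' Singular value decomposition of the between-block covariance matrix of
#' two column-centred data blocks; the first paired singular vectors give
#' block scores whose Pearson correlation `r` measures the strength of
#' covariation between the blocks (e.g. head shape vs the univariate
#' traits). Loading signs follow the convention that the largest-magnitude
#' element of the first block's loading vector is positive.
#'
#' @param block1 n x p matrix (e.g. trait block).
#' @param block2 n x q matrix (e.g. shape variables), same n >= 3.
#' @return An object of class `pls_result`: `r`, `u` and `v` (first
#'   singular vectors of each block), `d` (singular values),
#'   `scores1`/`scores2`, and the centred blocks (kept for permutation).
#' @export
two_block_pls <- function(block1, block2) {
  X <- as.matrix(block1); Y <- as.matrix(block2)
  n <- nrow(X)
  if (nrow(Y) != n) stop("blocks must have the same rows", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (any(apply(X, 2, sd) == 0) || any(apply(Y, 2, sd) == 0))
    stop("constant column in a block", call. = FALSE)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc) / (n - 1))
  u <- s$u[, 1]; v <- s$v[, 1]
  if (u[which.max(abs(u))] < 0) { u <- -u; v <- -v }
  s1 <- as.numeric(Xc %*% u); s2 <- as.numeric(Yc %*% v)
  structure(list(r = cor(s1, s2), u = u, v = v, d = s$d,
                 scores1 = s1, scores2 = s2, n = n, Xc = Xc, Yc = Yc),
            class = "pls_result")
}

#' @export
print.pls_result <- function(x, ...) {
  cat(sprintf("2B-PLS: n = %d, first-axis correlation r = %.3f", x$n, x$r))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g, Z = %.2f", x$p, x$Z))
  cat("\n")
  invisible(x)
}

pls_perm_stat <- function(Xc, Yc, n) {
  s <- svd(crossprod(Xc, Yc) / (n - 1))
  cor(as.numeric(Xc %*% s$u[, 1]), as.numeric(Yc %*% s$v[, 1]))
}

#' Permutation test and effect size for a 2B-PLS analysis
#'
#' Permutes the rows of the second block, recomputing the first-axis
#' correlation each time. The effect size is computed on the
#' variance-stabilized (Fisher-z) scale:
#' `Z = (z_obs - mean z_perm) / sd z_perm`; the p-value is the proportion
#' of permuted statistics at least as large as the observed one, with the
#' observed value included in the null.
#'
#' @param result a `pls_result`.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return The `pls_result` augmented with `p`, `Z`, `perm_z` (the permuted
#'   Fisher-z statistics) and `z_obs`.
#' @export
pls_permutation <- function(result, n_perm = 999L, seed = NULL) {
  stopifnot(inherits(result, "pls_result"))
  if (n_perm < 99L) stop("'n_perm' must be >= 99", call. = FALSE)
  fisher <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  with_seed(seed, {
    rp <- vapply(seq_len(n_perm), function(b)
      pls_perm_stat(result$Xc,
                    result$Yc[sample.int(result$n), , drop = FALSE],
                    result$n), numeric(1))
    zp <- fisher(rp)
    z_obs <- fisher(result$r)
    result$p <- (1 + sum(rp >= result$r)) / (n_perm + 1)
    s <- sd(zp)
    result$Z <- if (s > 0) (z_obs - mean(zp)) / s else 0
    result$perm_z <- zp
    result$z_obs <- z_obs
    result$n_perm <- n_perm
    result
  })
}

#' Two-sample comparison of 2B-PLS effect sizes
#'
#' Compares the permutation effect sizes of two analyses: the difference of
#' standardized effect sizes is scaled by the pooled standard errors of the
#' standardized permutation distributions (each ~1 by construction), and
#' referred to a standard normal (two-sided).
#'
#' @param a,b `pls_result` objects carrying permutation nulls
#'   (see [pls_permutation()]).
#' @return A list: `Z` (two-sample z-score), `p` (two-sided), and the two
#'   effect sizes.
#' @export
compare_pls <- function(a, b) {
  for (x in list(a, b)) if (is.null(x$perm_z))
    stop("run pls_permutation() on both results first", call. = FALSE)
  # each standardized effect size carries unit sampling variance from its
  # permutation distribution, so the pooled SE is sqrt(1 + 1)
  z <- (a$Z - b$Z) / sqrt(2)
  list(Z = z, p = 2 * pnorm(-abs(z)), Z1 = a$Z, Z2 = b$Z)
}

#' Leave-one-out sensitivity of the PLS correlation
#'
#' Recomputes the first-axis correlation with each observation removed; a
#' large drop pinpoints single influential individuals.
#'
#' @param result a `pls_result`.
#' @return Data frame with `dropped` (row index), `r`.
#' @export
pls_loo <- function(result) {
  stopifnot(inherits(result, "pls_result"))
  X <- result$Xc; Y <- result$Yc
  r <- vapply(seq_len(result$n), function(i) {
    Xi <- scale(X[-i, , drop = FALSE], scale = FALSE)
    Yi <- scale(Y[-i, , drop = FALSE], scale = FALSE)
    pls_perm_stat(Xi, Yi, result$n - 1L)
  }, numeric(1))
  data.frame(dropped = seq_len(result$n), r = r)
}
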