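#' Linear model on shape variables with randomized residual permutation
#'
#' Fits a sequential (type-I) multivariate linear model to shape variables
#' and assesses each term with the randomized residual permutation procedure
#' (RRPP): the null distribution of a term's sum of squares is built by
#' permuting the residuals of the reduced model containing all preceding
#' terms, holding the reduced-model fitted values fixed. Effect sizes are
#' standardized sums of squares, `Z = (SS_obs - mean SS_perm) / sd SS_perm`,
#' and p-values are the proportion of permuted statistics at least as large
#' as the observed one (which is included in the null, so `p >= 1/(n_perm+1)`).
#'
#' @param shapes n x p matrix of shape variables (e.g. [shape_matrix()]) or a
#'   `procrustes_result`.
#' @param data data frame of model covariates (n rows).
#' @param terms character vector of model terms in the order they enter the
#'   model (formula syntax, e.g. `c("log_size", "cross/family", "age")`).
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return A data frame of class `rrpp_table` with one row per term plus
#'   `Residuals` and `Total` rows: `df`, `SS`, `R2`, `Z`, `p`.
#' @export
rrpp_regression <- function(shapes, data, terms, n_perm = 999L, seed = NULL) {
  Y <- if (inherits(shapes, "procrustes_result")) shape_matrix(shapes) else
    as.matrix(shapes)
  n <- nrow(Y)
  if (nrow(data) != n) stop("'data' rows must match shapes", call. = FALSE)
  if (n_perm < 99L) stop("'n_perm' must be >= 99", call. = FALSE)
  # cumulative design matrices, intercept-only first
  forms <- c("1", vapply(seq_along(terms), function(i)
    paste(terms[seq_len(i)], collapse = " + "), character(1)))
  Xs <- lapply(forms, function(f)
    model.matrix(stats::as.formula(paste("~", f)), data = data))
  ranks <- integer(length(Xs))
  Hs <- vector("list", length(Xs))
  for (i in seq_along(Xs)) {
    q <- qr(Xs[[i]])
    ranks[i] <- q$rank
    if (i > 1L && ranks[i] == ranks[i - 1L])
      stop(sprintf("term '%s' is aliased with preceding terms",
                   terms[i - 1L]), call. = FALSE)
    Qm <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    Hs[[i]] <- tcrossprod(Qm)
  }
  if (ranks[length(ranks)] >= n)
    stop("saturated design: no residual degrees of freedom", call. = FALSE)
  nt <- length(terms)
  H_full <- Hs[[nt + 1L]]
  Ds <- lapply(seq_len(nt), function(i) Hs[[i + 1L]] - Hs[[i]])
  ss_term <- function(Yw, i) sum((Ds[[i]] %*% Yw)^2)
  SS <- vapply(seq_len(nt), function(i) ss_term(Y, i), numeric(1))
  SS_res <- sum(((diag(n) - H_full) %*% Y)^2)
  SS_tot <- sum(((diag(n) - Hs[[1L]]) %*% Y)^2)
  Zs <- ps <- rep(NA_real_, nt)
  with_seed(seed, {
    for (i in seq_len(nt)) {
      Fit <- Hs[[i]] %*% Y
      Res <- Y - Fit
      perm_ss <- numeric(n_perm + 1L)
      perm_ss[1L] <- SS[i]
      for (b in seq_len(n_perm)) {
        perm_ss[b + 1L] <- ss_term(Fit + Res[sample.int(n), , drop = FALSE], i)
      }
      s <- sd(perm_ss)
      Zs[i] <- if (s > 0) (SS[i] - mean(perm_ss)) / s else 0
      ps[i] <- mean(perm_ss >= SS[i])
    }
  })
  out <- data.frame(term = c(terms, "Residuals", "Total"),
                    df = c(diff(ranks), n - ranks[nt + 1L], n - 1L),
                    SS = c(SS, SS_res, SS_tot),
                    R2 = c(SS / SS_tot, SS_res / SS_tot, NA),
                    Z = c(Zs, NA, NA),
                    p = c(ps, NA, NA))
  class(out) <- c("rrpp_table", "data.frame")
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
print.rrpp_table <- function(x, digits = 3, ...) {
  cat("Randomized residual permutation procedure (", attr(x, "n_perm"),
      " permutations)\n", sep = "")
  print.data.frame(format(as.data.frame(x), digits = digits), row.names = FALSE)
  invisible(x)
}
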