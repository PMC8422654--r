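#' Fit the P-matrix model for one cross type
#'
#' Multi-response mixed model over the seven focal traits of one cross:
#' traits are mean-standardized (divided by their within-group means),
#' family enters as a fixed effect, the individual as a random effect, and
#' the residual covariance is pinned to a small fixed diagonal
#' (`1e-6` x trait variance) so the individual-level covariance absorbs the
#' phenotypic (co)variance — the posterior of that component is the P
#' matrix. Repeated latency records are averaged per individual first.
#'
#' @param traits a `trait_table` (long) or a wide per-individual data frame
#'   from [traits_wide()].
#' @param cross which cross type to fit.
#' @param n_iter,burn,thin,seed chain settings.
#' @param standardize divide each trait by its group mean first (default
#'   TRUE, matching the mean-standardization of the study).
#' @param prior inverse-Wishart prior; the default (`V = 1`, `nu` = number
#'   of traits) follows weakly informative practice for multi-response
#'   models. Note that on the mean-standardized scale (variances well below
#'   1) this prior pulls small variances upward at moderate sample sizes; a
#'   smaller `V` isolates the likelihood.
#' @return A `pmatrix_draws` object (see [assemble_P()]).
#' @export
fit_pmatrix <- function(traits, cross, n_iter = 3000L, burn = 800L,
                        thin = 2L, seed = 1L, standardize = TRUE,
                        prior = NULL) {
  wide <- if (inherits(traits, "trait_table")) traits_wide(traits) else traits
  wide <- wide[wide$cross == cross, , drop = FALSE]
  if (nrow(wide) < 10L) stop("too few individuals for a P fit", call. = FALSE)
  tr <- p_traits()
  if (!all(tr %in% names(wide)))
    stop("expected the 7 focal trait columns", call. = FALSE)
  means <- colMeans(wide[, tr])
  if (standardize) wide[, tr] <- sweep(wide[, tr], 2, means, "/")
  rvar <- apply(wide[, tr], 2, var)
  if (is.null(prior)) prior <- list(V = 1, nu = length(tr))
  sp <- model_spec(tr, fixed = ~ family, random = list(id = ~1),
                   prior = prior,
                   n_iter = n_iter, burn = burn, thin = thin, seed = seed,
                   r_fixed = diag(1e-6 * rvar))
  fit <- fit_gaussian(sp, wide)
  assemble_P(fit, trait_means = means, cross = cross)
}

#' Assemble posterior P-matrix draws from a fitted multi-response model
#'
#' Each stored draw of the individual-level covariance component is one
#' posterior draw of P. Draws that are numerically non-PSD are projected to
#' the PSD cone by clipping negative eigenvalues at zero; the count of
#' clipped draws is recorded.
#'
#' @param samples a `posterior_samples` from a multi-response fit with an
#'   individual random effect.
#' @param trait_means the group means used for mean-standardization.
#' @param cross cross label.
#' @param ind name of the individual random component.
#' @return An object of class `pmatrix_draws`: `draws` (kept x 7 x 7 array),
#'   `traits`, `cross`, `n_clipped`.
#' @export
assemble_P <- function(samples, trait_means = NULL, cross = NA_character_,
                       ind = "id") {
  arr <- samples$vcv[[ind]]
  if (is.null(arr)) stop("no individual random component", call. = FALSE)
  tr <- dimnames(arr)[[2]]
  if (length(tr) != length(p_traits()))
    stop(sprintf("expected %d traits, got %d", length(p_traits()),
                 length(tr)), call. = FALSE)
  n_clipped <- 0L
  for (i in seq_len(dim(arr)[1])) {
    m <- arr[i, , ]
    ev <- eigen(0.5 * (m + t(m)), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 0) {
      arr[i, , ] <- psd_clip(m)
      n_clipped <- n_clipped + 1L
    }
  }
  structure(list(draws = arr, traits = tr, cross = cross,
                 trait_means = trait_means, n_clipped = n_clipped),
            class = "pmatrix_draws")
}

#' @export
print.pmatrix_draws <- function(x, ...) {
  cat(sprintf("P-matrix posterior for cross %s: %d draws over %d traits (%d clipped to PSD)\n",
              x$cross, dim(x$draws)[1], length(x$traits), x$n_clipped))
  invisible(x)
}

#' Total variance of a covariance matrix
#'
#' Sum of the eigenvalues (equal to the trace): the overall phenotypic
#' variance captured by the matrix.
#'
#' @param P symmetric square matrix.
#' @return Numeric scalar.
#' @export
vtot <- function(P) {
  if (!is_square_symmetric(P)) stop("asymmetric input", call. = FALSE)
  sum(eigen(0.5 * (P + t(P)), symmetric = TRUE, only.values = TRUE)$values)
}

#' Eccentricity of a covariance matrix
#'
#' Ratio of the first two eigenvalues; large values indicate a constrained,
#' cigar-shaped covariance structure.
#'
#' @param P symmetric square matrix of rank >= 2.
#' @return Numeric scalar >= 1.
#' @export
eccentricity <- function(P) {
  if (!is_square_symmetric(P)) stop("asymmetric input", call. = FALSE)
  ev <- eigen(0.5 * (P + t(P)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-12) stop("degenerate matrix: second eigenvalue ~ 0",
                           call. = FALSE)
  ev[1] / ev[2]
}

#' Angle between the leading eigenvectors of two covariance matrices
#'
#' `acos(|v1 . v2|)` in degrees, sign-invariant, so the angle lies in
#' `[0, 90]`. When a matrix has a (numerically) tied leading eigenvalue the
#' returned value carries the attribute `degenerate = TRUE`.
#'
#' @param P1,P2 symmetric square matrices.
#' @return Angle in degrees.
#' @export
pmat_angle <- function(P1, P2) {
  if (!is_square_symmetric(P1) || !is_square_symmetric(P2))
    stop("asymmetric input", call. = FALSE)
  e1 <- eigen(0.5 * (P1 + t(P1)), symmetric = TRUE)
  e2 <- eigen(0.5 * (P2 + t(P2)), symmetric = TRUE)
  deg <- FALSE
  for (e in list(e1, e2)) {
    gap <- (e$values[1] - e$values[2]) / max(e$values[1], 1e-300)
    if (is.finite(gap) && gap < 1e-8) deg <- TRUE
  }
  v1 <- e1$vectors[, 1]; v2 <- e2$vectors[, 1]
  ang <- acos(min(1, abs(sum(v1 * v2)))) * 180 / pi
  if (deg) attr(ang, "degenerate") <- TRUE
  ang
}

#' Posterior summaries of P-matrix size, eccentricity and orientation
#'
#' Computes `V_tot` and eccentricity per draw of one P, and the eigenvector
#' angle theta per paired draw of two Ps (paired by draw index), returning
#' posterior modes and 95% HPD intervals.
#'
#' @param P a `pmatrix_draws`.
#' @param P2 optional second `pmatrix_draws` for the angle summary.
#' @return Data frame with `stat`, `mode`, `lo`, `hi`.
#' @export
pmatrix_summary <- function(P, P2 = NULL) {
  stopifnot(inherits(P, "pmatrix_draws"))
  nd <- dim(P$draws)[1]
  vt <- vapply(seq_len(nd), function(i) vtot(P$draws[i, , ]), numeric(1))
  om <- vapply(seq_len(nd), function(i) eccentricity(P$draws[i, , ]),
               numeric(1))
  out <- rbind(summ_stat(vt, "V_tot"), summ_stat(om, "eccentricity"))
  if (!is.null(P2)) {
    nd2 <- min(nd, dim(P2$draws)[1])
    th <- vapply(seq_len(nd2), function(i)
      as.numeric(pmat_angle(P$draws[i, , ], P2$draws[i, , ])), numeric(1))
    out <- rbind(out, summ_stat(th, "theta"))
  }
  rownames(out) <- NULL
  out
}

# mode + 95% HPD, falling back to mean/range for very short samples
robust_ci <- function(x) {
  if (length(x) >= 100L) hpd_interval(x) else range(x)
}

summ_stat <- function(x, name) {
  ci <- robust_ci(x)
  m <- if (length(x) >= 100L) posterior_mode(x) else mean(x)
  data.frame(stat = name, mode = m, lo = ci[1], hi = ci[2])
}

# family-adjusted trait residuals on the standardized scale (covariance
# inputs for the resampling nulls)
family_adjusted <- function(wide, standardize = TRUE) {
  tr <- p_traits()
  out <- wide
  for (cc in unique(wide$cross)) {
    sel <- wide$cross == cc
    m <- colMeans(wide[sel, tr])
    if (standardize) out[sel, tr] <- sweep(wide[sel, tr], 2, m, "/")
    fam <- factor(out$family[sel])
    for (t in tr) {
      r <- if (nlevels(fam) > 1L)
        stats::residuals(stats::lm(out[sel, t] ~ fam)) else
          out[sel, t] - mean(out[sel, t])
      out[sel, t] <- r + mean(out[sel, t])
    }
  }
  out
}

#' Resampling null for the angle between leading eigenvectors
#'
#' Builds the null distribution of theta used to judge an observed angle:
#' repeatedly sample `n_draw` individuals from the pooled pair of cross
#' types, compute the sample covariance of their family-adjusted,
#' mean-standardized trait values (a "random" P), and record the angle
#' between its leading eigenvector and the focal leading eigenvector. When
#' fewer than `n_draw` individuals are available, sampling falls back to
#' with-replacement and the result is flagged.
#'
#' @param wide per-individual wide trait data ([traits_wide()]) for the two
#'   cross types being compared.
#' @param focal_vector leading eigenvector the angles are measured against;
#'   either a single vector or a matrix of per-posterior-draw leading
#'   eigenvectors (rows). Supplying the posterior draws (see
#'   [leading_eigenvectors()]) propagates the focal P's posterior
#'   uncertainty into the null, matching the uncertainty carried by the
#'   observed per-draw angles.
#' @param n_draw individuals per resample (default 150).
#' @param n_rep number of resamples.
#' @param seed integer seed.
#' @return A list: `angles`, `ci` (95% HPD), `with_replacement` flag.
#' @export
random_angle_null <- function(wide, focal_vector, n_draw = 150L,
                              n_rep = 500L, seed = NULL) {
  tr <- p_traits()
  adj <- family_adjusted(wide)
  n <- nrow(adj)
  wr <- n < n_draw
  if (wr) warning("fewer than ", n_draw,
                  " individuals: resampling with replacement")
  X <- as.matrix(adj[, tr])
  if (is.matrix(focal_vector)) {
    F <- focal_vector / sqrt(rowSums(focal_vector^2))
  } else {
    F <- matrix(focal_vector / sqrt(sum(focal_vector^2)), nrow = 1)
  }
  with_seed(seed, {
    angles <- vapply(seq_len(n_rep), function(b) {
      idx <- sample.int(n, n_draw, replace = wr)
      v <- eigen(cov(X[idx, ]), symmetric = TRUE)$vectors[, 1]
      f <- F[1L + (b - 1L) %% nrow(F), ]
      acos(min(1, abs(sum(v * f)))) * 180 / pi
    }, numeric(1))
    list(angles = angles, ci = robust_ci(angles),
         with_replacement = wr)
  })
}

#' Per-draw leading eigenvectors of a P posterior
#'
#' @param P a `pmatrix_draws`.
#' @return Matrix (draws x traits) of unit leading eigenvectors.
#' @export
leading_eigenvectors <- function(P) {
  stopifnot(inherits(P, "pmatrix_draws"))
  t(vapply(seq_len(dim(P$draws)[1]), function(i)
    eigen(P$draws[i, , ], symmetric = TRUE)$vectors[, 1],
    numeric(length(P$traits))))
}

#' Krzanowski common subspaces across groups
#'
#' For each posterior draw, takes the first `k` eigenvectors of every
#' group's P, forms the sum of the subspace projectors
#' `H = sum_t A_t A_t'`, and records the eigenvalues of `H`. Eigenvalues
#' close to the number of groups indicate a shared subspace.
#'
#' @param P_list list of `pmatrix_draws`, one per group (>= 2 groups).
#' @param k subspace dimension; must satisfy `k <= floor(q / 2)`.
#' @return An object of class `subspace_result`: `eigenvalues` (draws x q
#'   matrix), `summary` (mode + 95% HPD per eigenvalue), `H_mean`,
#'   `eigenvectors` (of the mean H), `k`, `n_groups`.
#' @export
krzanowski_H <- function(P_list, k = 3L) {
  if (length(P_list) < 2L) stop(">= 2 groups required", call. = FALSE)
  q <- length(P_list[[1]]$traits)
  if (k > floor(q / 2))
    stop(sprintf("k must be <= floor(%d/2) = %d", q, floor(q / 2)),
         call. = FALSE)
  nd <- min(vapply(P_list, function(p) dim(p$draws)[1], 1L))
  ng <- length(P_list)
  ev <- matrix(NA_real_, nd, q)
  H_sum <- matrix(0, q, q)
  for (i in seq_len(nd)) {
    H <- matrix(0, q, q)
    for (p in P_list) {
      A <- eigen(p$draws[i, , ], symmetric = TRUE)$vectors[, seq_len(k),
                                                           drop = FALSE]
      H <- H + tcrossprod(A)
    }
    ev[i, ] <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    H_sum <- H_sum + H
  }
  H_mean <- H_sum / nd
  summ <- do.call(rbind, lapply(seq_len(q), function(j)
    summ_stat(ev[, j], paste0("lambda", j))))
  structure(list(eigenvalues = ev, summary = summ, H_mean = H_mean,
                 eigenvectors = eigen(H_mean, symmetric = TRUE)$vectors,
                 k = k, n_groups = ng),
            class = "subspace_result")
}

#' @export
print.subspace_result <- function(x, ...) {
  cat(sprintf("Krzanowski common subspaces: k = %d, %d groups\n", x$k,
              x$n_groups))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Randomized-group null for the common-subspace eigenvalues
#'
#' Shuffles individuals' cross labels, rebuilds a sample-covariance P per
#' pseudo-group (family-adjusted, mean-standardized trait values), and
#' recomputes the `H` eigenvalues, giving the null distribution against
#' which the observed eigenvalue credible intervals are compared.
#'
#' @param wide per-individual wide trait data for all crosses.
#' @param k subspace dimension.
#' @param n_rep number of label permutations.
#' @param seed integer seed.
#' @return A list: `eigenvalues` (n_rep x q), `ci` (95% HPD per eigenvalue).
#' @export
subspace_null <- function(wide, k = 3L, n_rep = 500L, seed = NULL) {
  tr <- p_traits()
  q <- length(tr)
  if (k > floor(q / 2)) stop("k out of bound", call. = FALSE)
  adj <- family_adjusted(wide)
  X <- as.matrix(adj[, tr])
  gr <- as.factor(adj$cross)
  with_seed(seed, {
    ev <- t(vapply(seq_len(n_rep), function(b) {
      gp <- sample(gr)
      H <- matrix(0, q, q)
      for (g in levels(gp)) {
        A <- eigen(cov(X[gp == g, , drop = FALSE]),
                   symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
        H <- H + tcrossprod(A)
      }
      eigen(H, symmetric = TRUE, only.values = TRUE)$values
    }, numeric(q)))
    list(eigenvalues = ev,
         ci = t(apply(ev, 2, robust_ci)))
  })
}

#' Project P matrices onto a reference three-axis subspace
#'
#' Projects each cross's posterior P (elementwise posterior mode, clipped to
#' PSD) onto the first three eigenvectors of the reference cross's P, for
#' ellipsoid visualisation, and reports the fraction of each matrix's total
#' variance captured by the reference axes.
#'
#' @param P_list named list of `pmatrix_draws`.
#' @param reference name of the reference cross (default the first).
#' @return A list per cross: `projected` (3 x 3 covariance in the reference
#'   axes), `axes_lengths` (sqrt eigenvalues), `axes` (3-D orientation),
#'   `captured` (fraction of V_tot captured). JSON-serializable.
#' @export
project_ellipsoids <- function(P_list, reference = names(P_list)[1]) {
  stopifnot(reference %in% names(P_list))
  pmode <- function(P) {
    nd <- dim(P$draws)[1]
    q <- length(P$traits)
    m <- matrix(0, q, q)
    for (i in seq_len(q)) for (j in seq_len(i)) {
      v <- posterior_mode(P$draws[, i, j])
      m[i, j] <- m[j, i] <- v
    }
    psd_clip(m)
  }
  modes <- lapply(P_list, pmode)
  E <- eigen(modes[[reference]], symmetric = TRUE)$vectors[, 1:3]
  out <- lapply(names(P_list), function(cc) {
    P <- modes[[cc]]
    proj <- t(E) %*% P %*% E
    e <- eigen(proj, symmetric = TRUE)
    list(cross = cc,
         projected = proj,
         axes_lengths = sqrt(pmax(e$values, 0)),
         axes = e$vectors,
         captured = sum(diag(proj)) / vtot(P))
  })
  names(out) <- names(P_list)
  out
}
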