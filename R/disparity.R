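#' Morphological disparity (Procrustes variance) per group
#'
#' Disparity of a group is the mean squared Procrustes distance of its
#' members to the group mean shape.
#'
#' @param shapes n x p matrix of shape variables (see [shape_matrix()]) or a
#'   `procrustes_result`.
#' @param groups factor of group labels, length n.
#' @return Named numeric vector of per-group disparities.
#' @export
procrustes_variance <- function(shapes, groups) {
  Y <- if (inherits(shapes, "procrustes_result")) shape_matrix(shapes) else
    as.matrix(shapes)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop(">= 2 groups are required", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs >= 2 specimens", call. = FALSE)
  vapply(levels(groups), function(g) {
    Yg <- Y[groups == g, , drop = FALSE]
    mean(rowSums(sweep(Yg, 2, colMeans(Yg))^2))
  }, numeric(1))
}

#' Permutation test of pairwise disparity differences
#'
#' Absolute pairwise differences in Procrustes variance, with p-values from
#' permuting group labels (the observed value is included in the null).
#'
#' @inheritParams procrustes_variance
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A list: `disparity` (per group), `pairwise` (data frame with
#'   `group1`, `group2`, `abs_diff`, `p`), `n_perm`.
#' @export
disparity_test <- function(shapes, groups, n_perm = 999L, seed = NULL) {
  Y <- if (inherits(shapes, "procrustes_result")) shape_matrix(shapes) else
    as.matrix(shapes)
  groups <- as.factor(groups)
  obs <- procrustes_variance(Y, groups)
  cmb <- utils::combn(levels(groups), 2)
  obs_diff <- abs(obs[cmb[1, ]] - obs[cmb[2, ]])
  with_seed(seed, {
    ge <- rep(1L, ncol(cmb))  # observed counts toward the null
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      d <- procrustes_variance(Y, gp)
      ge <- ge + as.integer(abs(d[cmb[1, ]] - d[cmb[2, ]]) >= obs_diff)
    }
    list(disparity = obs,
         pairwise = data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                               abs_diff = as.numeric(obs_diff),
                               p = as.numeric(ge / (n_perm + 1))),
         n_perm = n_perm)
  })
}

#' Phenotypic trajectory analysis over developmental stages
#'
#' Each group's trajectory is the sequence of its stage mean shapes. Groups
#' are compared pairwise on (i) path length (summed distances between
#' consecutive stage means), (ii) direction (angle in degrees between the
#' first principal axes of the stage means) and (iii) trajectory shape
#' (Procrustes distance between the size-standardized trajectories).
#' Significance comes from permuting group labels among individuals.
#'
#' @param shapes n x p shape-variable matrix or `procrustes_result`.
#' @param groups factor of group labels (length n).
#' @param stages factor/vector of stage labels (length n); every group must
#'   be observed at every stage.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A list with `trajectories` (list of stage-mean matrices),
#'   `path_length` (per group) and `pairwise` (data frame of observed
#'   differences and permutation p-values for the three attributes).
#' @export
trajectory_analysis <- function(shapes, groups, stages, n_perm = 999L,
                                seed = NULL) {
  Y <- if (inherits(shapes, "procrustes_result")) shape_matrix(shapes) else
    as.matrix(shapes)
  groups <- as.factor(groups)
  stages <- as.factor(stages)
  if (any(table(groups, stages) == 0))
    stop("missing group x stage cell", call. = FALSE)
  stats_fun <- function(gr) {
    trajs <- lapply(levels(gr), function(g) {
      t(vapply(levels(stages), function(s)
        colMeans(Y[gr == g & stages == s, , drop = FALSE]),
        numeric(ncol(Y))))
    })
    names(trajs) <- levels(gr)
    pl <- vapply(trajs, function(m) sum(sqrt(rowSums(diff(m)^2))), numeric(1))
    dirs <- lapply(trajs, function(m) {
      v <- svd(sweep(m, 2, colMeans(m)))$v[, 1]
      v / sqrt(sum(v^2))
    })
    cmb <- utils::combn(levels(gr), 2)
    res <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ])
    res$d_length <- abs(pl[cmb[1, ]] - pl[cmb[2, ]])
    res$d_angle <- vapply(seq_len(ncol(cmb)), function(j) {
      ct <- abs(sum(dirs[[cmb[1, j]]] * dirs[[cmb[2, j]]]))
      acos(min(1, ct)) * 180 / pi
    }, numeric(1))
    res$d_shape <- vapply(seq_len(ncol(cmb)), function(j) {
      z1 <- scale(trajs[[cmb[1, j]]], scale = FALSE)
      z2 <- scale(trajs[[cmb[2, j]]], scale = FALSE)
      s1 <- sqrt(sum(z1^2)); s2 <- sqrt(sum(z2^2))
      if (s1 == 0 || s2 == 0) return(0)
      z1 <- z1 / s1; z2 <- z2 / s2
      # optimal orthogonal alignment of the two trajectories
      sv <- svd(crossprod(z2, z1))
      sqrt(max(0, 2 - 2 * sum(sv$d)))
    }, numeric(1))
    list(trajs = trajs, pl = pl, res = res)
  }
  obs <- stats_fun(groups)
  with_seed(seed, {
    ge <- matrix(1L, nrow(obs$res), 3)
    for (b in seq_len(n_perm)) {
      # permute group labels within stage so every group x stage cell stays
      # populated
      gp <- groups
      for (s in levels(stages)) {
        sel <- stages == s
        gp[sel] <- sample(groups[sel])
      }
      perm <- stats_fun(gp)
      ge <- ge + (as.matrix(perm$res[, c("d_length", "d_angle", "d_shape")]) >=
                    as.matrix(obs$res[, c("d_length", "d_angle", "d_shape")]))
    }
    pv <- ge / (n_perm + 1)
    out <- obs$res
    out$p_length <- pv[, 1]; out$p_angle <- pv[, 2]; out$p_shape <- pv[, 3]
    list(trajectories = obs$trajs, path_length = obs$pl, pairwise = out,
         n_perm = n_perm)
  })
}
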