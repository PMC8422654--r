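test_that("matrix size, eccentricity and angle satisfy their identities", {
  I7 <- diag(7)
  expect_equal(vtot(I7), 7.0)
  expect_equal(vtot(diag(c(1, 2, 3, 0, 0, 0, 0))), 6.0)
  expect_equal(eccentricity(I7), 1.0)
  expect_equal(eccentricity(diag(c(4, 2, 1, 1, 1, 1, 1))), 2.0)
  P <- diag(c(5, 3, 1, 1, 1, 1, 1))
  expect_equal(as.numeric(pmat_angle(P, P)), 0.0)
  expect_equal(as.numeric(pmat_angle(diag(c(4, 1, 1, 1, 1, 1, 1)),
                                     diag(c(1, 4, 1, 1, 1, 1, 1)))), 90.0)
  v <- c(1, 1, 0, 0, 0, 0, 0) / sqrt(2)
  P45 <- 4 * tcrossprod(v) + diag(7) * 0.5
  expect_equal(as.numeric(pmat_angle(P45, diag(c(4, 1, 1, 1, 1, 1, 1) * 0.5 +
                                                 c(4, 0, 0, 0, 0, 0, 0)))),
               45, tolerance = 1e-8)
  expect_error(vtot(matrix(1:4, 2) + diag(c(0, 5))), "asymmetric")
  expect_error(eccentricity(tcrossprod(rep(1, 3))), "degenerate")
  a <- pmat_angle(diag(c(1, 1, 0.5)), diag(c(2, 1, 1)))
  expect_true(isTRUE(attr(a, "degenerate")))
})

test_that("vtot equals the trace and eccentricity is rotation-invariant", {
  set.seed(1)
  for (i in 1:200) {
    P <- random_psd(7)
    expect_equal(vtot(P), sum(diag(P)), tolerance = 1e-10)
    Q <- qr.Q(qr(matrix(rnorm(49), 7)))
    expect_equal(eccentricity(Q %*% P %*% t(Q)), eccentricity(P),
                 tolerance = 1e-8)
  }
  # theta is symmetric in its arguments
  P1 <- random_psd(7); P2 <- random_psd(7)
  expect_equal(as.numeric(pmat_angle(P1, P2)),
               as.numeric(pmat_angle(P2, P1)), tolerance = 1e-10)
})

test_that("mean-standardization makes P scale-invariant and PSD clipping works", {
  d <- sim_design(n_families_per_cross = 3, n_offspring_per_family = 20)
  p <- sim_params(d)
  tt <- simulate_traits(generate_design(d, 1), p, seed = 2)
  P1 <- fit_pmatrix(tt, "PL", n_iter = 600, burn = 200, thin = 2, seed = 3)
  tt2 <- tt
  sel <- tt2$trait == "sl_d1"
  tt2$value[sel] <- tt2$value[sel] * 2  # doubling the raw scale
  P2 <- fit_pmatrix(tt2, "PL", n_iter = 600, burn = 200, thin = 2, seed = 3)
  expect_equal(P1$draws, P2$draws, tolerance = 1e-8)
  # clipping: a slightly negative eigenvalue is lifted to >= 0
  m <- diag(c(1, 1, 1, 1, 1, 1, -1e-12))
  mc <- charrdiv:::psd_clip(m)
  expect_gte(min(eigen(mc, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_error(assemble_P(structure(list(vcv = list(id = array(1, c(200, 2, 2)))),
                                    class = "posterior_samples")),
               "expected 7")
})

test_that("generating individual covariance is recovered at study scale", {
  d <- sim_design(n_families_per_cross = 3, n_offspring_per_family = 40)
  truth <- diag(1:7) / 10
  p <- shared_cov_params(d, truth)
  tt <- simulate_traits(generate_design(d, 5), p, seed = 6)
  # single pooled fit across all 360 individuals; weak prior isolates the
  # likelihood (the default follows the study and is deliberately stronger)
  wide <- traits_wide(tt)
  wide$cross <- "all"
  Pd <- fit_pmatrix(wide, "all", n_iter = 1500, burn = 400, thin = 2,
                    seed = 7, standardize = FALSE,
                    prior = list(V = 0.01, nu = 7.01))
  Pm <- apply(Pd$draws, c(2, 3), mean)
  expect_lt(max(abs(diag(Pm) - diag(truth)) / diag(truth)), 0.2)
})

test_that("Krzanowski H matches its projector oracle and identities", {
  mk_draws <- function(mats) {
    arr <- array(NA_real_, c(length(mats), 7, 7),
                 dimnames = list(NULL, p_traits(), p_traits()))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
    structure(list(draws = arr, traits = p_traits(), cross = "x",
                   n_clipped = 0L), class = "pmatrix_draws")
  }
  set.seed(8)
  P <- random_psd(7)
  res <- krzanowski_H(list(mk_draws(list(P)), mk_draws(list(P)),
                           mk_draws(list(P))), k = 3)
  expect_equal(res$eigenvalues[1, 1:3], rep(3, 3), tolerance = 1e-9)
  # orthogonal k = 1 subspaces -> eigenvalues (1, 1)
  Pa <- diag(c(4, 1, 1, 1, 1, 1, 1)); Pb <- diag(c(1, 4, 1, 1, 1, 1, 1))
  res2 <- krzanowski_H(list(mk_draws(list(Pa)), mk_draws(list(Pb))), k = 1)
  expect_equal(res2$eigenvalues[1, 1:2], c(1, 1), tolerance = 1e-9)
  expect_error(krzanowski_H(list(mk_draws(list(Pa)), mk_draws(list(Pb))),
                            k = 4), "k must be")
  # random groups: bounded by the group count and equal to the brute-force
  # projector sum
  mats <- lapply(1:3, function(i) random_psd(7))
  res3 <- krzanowski_H(lapply(mats, function(m) mk_draws(list(m))), k = 3)
  H <- Reduce(`+`, lapply(mats, function(m) {
    A <- eigen(m, symmetric = TRUE)$vectors[, 1:3]
    A %*% t(A)
  }))
  expect_equal(res3$eigenvalues[1, ],
               eigen(H, symmetric = TRUE, only.values = TRUE)$values,
               tolerance = 1e-9)
  expect_true(all(res3$eigenvalues <= 3 + 1e-9))
  expect_true(all(res3$eigenvalues >= -1e-9))
})

test_that("subspace label permutation preserves group sizes", {
  d <- sim_design(n_families_per_cross = 2, n_offspring_per_family = 12)
  p <- sim_params(d)
  tt <- simulate_traits(generate_design(d, 1), p, seed = 9)
  wide <- traits_wide(tt)
  n0 <- table(wide$cross)
  nul <- subspace_null(wide, k = 3, n_rep = 20, seed = 10)
  expect_equal(dim(nul$eigenvalues), c(20L, 7L))
  expect_true(all(nul$eigenvalues <= 3 + 1e-9))
  # permuting labels can never change the per-group totals
  set.seed(10)
  gp <- sample(wide$cross)
  expect_equal(as.vector(table(gp)), as.vector(n0))
})

test_that("ellipsoid projection captures the expected variance fractions", {
  mk <- function(m, n = 150) {
    arr <- array(NA_real_, c(n, 7, 7),
                 dimnames = list(NULL, p_traits(), p_traits()))
    for (i in seq_len(n)) arr[i, , ] <- m
    structure(list(draws = arr, traits = p_traits(), cross = "x",
                   n_clipped = 0L), class = "pmatrix_draws")
  }
  P <- diag(c(5, 4, 3, 2, 1, 1, 1))
  pr <- project_ellipsoids(list(A = mk(P)), reference = "A")
  expect_equal(pr$A$captured, (5 + 4 + 3) / 17, tolerance = 1e-8)
  iso <- project_ellipsoids(list(A = mk(diag(7))), reference = "A")
  expect_equal(iso$A$captured, 3 / 7, tolerance = 1e-8)
  # invariance to trait reordering
  set.seed(11)
  M <- random_psd(7)
  perm <- sample(7)
  pr1 <- project_ellipsoids(list(A = mk(M)), reference = "A")
  pr2 <- project_ellipsoids(list(A = mk(M[perm, perm])), reference = "A")
  expect_equal(pr1$A$captured, pr2$A$captured, tolerance = 1e-8)
})

test_that("angle nulls separate shared from orthogonal generating axes", {
  d <- sim_design(n_families_per_cross = 3, n_offspring_per_family = 40)
  shared <- diag(c(6, 1, 1, 1, 1, 1, 1)) / 10
  p_shared <- shared_cov_params(d, shared)
  tt <- simulate_traits(generate_design(d, 12), p_shared, seed = 13)
  wide <- traits_wide(tt)
  two <- wide[wide$cross %in% c("PL", "SB"), ]
  # posterior theta between the two crosses, as the pipeline computes it
  P_pl <- fit_pmatrix(tt, "PL", n_iter = 900, burn = 300, thin = 2, seed = 18)
  P_sb <- fit_pmatrix(tt, "SB", n_iter = 900, burn = 300, thin = 2, seed = 19)
  th <- pmatrix_summary(P_pl, P_sb)
  th <- th[th$stat == "theta", ]
  nul <- random_angle_null(two, leading_eigenvectors(P_pl), n_rep = 200,
                           seed = 14)
  # shared axes: the observed CrI overlaps the null CrI
  expect_lte(max(th$lo, nul$ci[1]), min(th$hi, nul$ci[2]))
  # orthogonal, highly eccentric axes: observed angle beyond the null
  cov_list <- list(PL = diag(c(8, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2)) / 10,
                   SB = diag(c(0.2, 8, 0.2, 0.2, 0.2, 0.2, 0.2)) / 10,
                   F1 = diag(c(8, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2)) / 10)
  p_orth <- sim_params(d, ind_cov = cov_list,
                       family_cov = diag(1e-10, 7),
                       resid_cov = diag(1e-10, 7))
  tt2 <- simulate_traits(generate_design(d, 15), p_orth, seed = 16)
  wide2 <- traits_wide(tt2)
  two2 <- wide2[wide2$cross %in% c("PL", "SB"), ]
  S2_pl <- cov(as.matrix(two2[two2$cross == "PL", p_traits()]))
  S2_sb <- cov(as.matrix(two2[two2$cross == "SB", p_traits()]))
  obs2 <- as.numeric(pmat_angle(S2_pl, S2_sb))
  focal2 <- eigen(S2_pl, symmetric = TRUE)$vectors[, 1]
  nul2 <- random_angle_null(two2, focal2, n_rep = 200, seed = 17)
  expect_gt(obs2, quantile(nul2$angles, 0.975))
  expect_identical(random_angle_null(two2, focal2, n_rep = 120, seed = 3),
                   random_angle_null(two2, focal2, n_rep = 120, seed = 3))
})
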