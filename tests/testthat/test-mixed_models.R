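test_that("posterior mode and HPD match analytic normal quantities", {
  set.seed(1)
  x <- rnorm(1e5)
  expect_equal(posterior_mode(x), 0, tolerance = 0.05)
  ci <- hpd_interval(x, 0.95)
  expect_equal(ci[1], -1.96, tolerance = 0.05)
  expect_equal(ci[2], 1.96, tolerance = 0.05)
  cst <- rep(3.2, 200)
  expect_equal(posterior_mode(cst), 3.2)
  expect_equal(hpd_interval(cst), c(3.2, 3.2))
  expect_error(posterior_mode(rnorm(50)), "100")
  expect_error(hpd_interval(rnorm(50)), "100")
  # HPD is never wider than the equal-tailed interval on skewed draws
  y <- exp(rnorm(2e4))
  hp <- hpd_interval(y, 0.9)
  et <- quantile(y, c(0.05, 0.95))
  expect_lte(diff(hp), unname(diff(et)))
})

test_that("fixed effects agree with OLS when the model is plain regression", {
  set.seed(2)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 2 * d$x + rnorm(n)
  fit <- fit_gaussian(model_spec("y", ~x, n_iter = 3000, burn = 500,
                                 thin = 5, seed = 3), d)
  expect_equal(fit$n_kept, (3000 - 500) / 5)
  ols <- summary(stats::lm(y ~ x, d))$coefficients
  ps <- posterior_summary(fit)
  for (j in 1:2) {
    post_sd <- sd(fit$b[, j])
    expect_lt(abs(ps$mode[j] - ols[j, 1]), 2 * post_sd)
  }
})

test_that("random-intercept variances are recovered and match lme4", {
  skip_if_not_installed("lme4")
  set.seed(4)
  nid <- 150
  u <- rnorm(nid, 0, sqrt(2))
  d <- data.frame(id = factor(rep(seq_len(nid), each = 3)))
  d$y <- 0.5 + u[as.integer(d$id)] + rnorm(nrow(d))
  fit <- fit_gaussian(model_spec("y", ~1, random = list(id = ~1),
                                 n_iter = 4000, burn = 1000, thin = 5,
                                 seed = 5), d)
  vi <- fit$vcv$id[, 1, 1]
  lf <- lme4::lmer(y ~ 1 + (1 | id), d)
  vl <- as.data.frame(lme4::VarCorr(lf))$vcov
  # Gibbs posterior mode close to the REML point estimates
  expect_equal(posterior_mode(vi), vl[1], tolerance = 0.25)
  expect_equal(posterior_mode(fit$resid[, 1, 1]), vl[2], tolerance = 0.15)
  ci <- hpd_interval(vi)
  expect_lt(ci[1], 2)  # 95% CrI covers the generating variance
  expect_gt(ci[2], 2)
})

test_that("covariance draws are symmetric PSD and counts match settings", {
  set.seed(6)
  nid <- 60
  U <- MASS::mvrnorm(nid, c(0, 0), matrix(c(1, .4, .4, 1), 2))
  d <- data.frame(id = factor(rep(seq_len(nid), 2)))
  d$t1 <- 1 + U[as.integer(d$id), 1] + rnorm(nrow(d), 0, 1e-3)
  d$t2 <- 2 + U[as.integer(d$id), 2] + rnorm(nrow(d), 0, 1e-3)
  fit <- fit_gaussian(model_spec(c("t1", "t2"), ~1,
                                 random = list(id = ~1),
                                 prior = list(V = 1, nu = 2),
                                 n_iter = 1500, burn = 400, thin = 2,
                                 seed = 7,
                                 r_fixed = diag(1e-6, 2)), d)
  expect_equal(fit$n_kept, floor((1500 - 400) / 2))
  for (i in seq_len(fit$n_kept)) {
    G <- fit$vcv$id[i, , ]
    expect_equal(G, t(G), tolerance = 1e-10)
    expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("the prior dominates when the data are tiny", {
  set.seed(8)
  d <- data.frame(id = factor(rep(1:3, each = 2)))
  d$y <- rnorm(6, 0, 0.01)
  fit <- fit_gaussian(model_spec("y", ~1, random = list(id = ~1),
                                 prior = list(V = 5, nu = 50),
                                 n_iter = 2000, burn = 500, thin = 3,
                                 seed = 9), d)
  # posterior mean of both variance components approaches the prior scale
  expect_equal(mean(fit$vcv$id[, 1, 1]), 5, tolerance = 0.5)
  expect_equal(mean(fit$resid[, 1, 1]), 5, tolerance = 0.5)
})

test_that("chains are reproducible and degenerate inputs error", {
  d <- data.frame(x = rnorm(30), y = rnorm(30))
  sp <- model_spec("y", ~x, n_iter = 500, burn = 100, thin = 1, seed = 10)
  expect_identical(fit_gaussian(sp, d)$b, fit_gaussian(sp, d)$b)
  d$z <- 1
  expect_error(fit_gaussian(model_spec("z", ~x, n_iter = 500, burn = 100),
                            d), "zero-variance")
  d$x2 <- d$x
  expect_error(fit_gaussian(model_spec("y", ~x + x2, n_iter = 500,
                                       burn = 100), d), "rank-deficient")
  expect_error(model_spec("y", n_iter = 100, burn = 200), "exceed")
  expect_error(fit_gaussian(model_spec(c("y", "x"), ~1,
                                       prior = list(V = 1, nu = 0.002),
                                       n_iter = 500, burn = 100), d),
               "nu")
})

test_that("binary fits handle degenerate and symmetric cases", {
  set.seed(11)
  d <- data.frame(y = rep(0L, 40), id = factor(rep(1:20, 2)))
  fit0 <- fit_binary(model_spec("y", ~1, random = list(id = ~1),
                                n_iter = 800, burn = 200, thin = 2,
                                seed = 12), d)
  expect_lt(mean(fit0$b[, 1]), -0.5)  # mass on negative latent mean
  expect_error(fit_binary(model_spec("y", ~1, n_iter = 500, burn = 100),
                          data.frame(y = c(0, 1, 2))), "only 0 and 1")
  # probit symmetry: latent mean 0 predicts probability one half
  expect_equal(pnorm(0), 0.5)
  set.seed(13)
  nid <- 200
  u <- rnorm(nid, 0, 1)
  d2 <- data.frame(id = factor(rep(seq_len(nid), each = 3)))
  d2$y <- as.integer(u[as.integer(d2$id)] + rnorm(nrow(d2)) > 0)
  fit <- fit_binary(model_spec("y", ~1, random = list(id = ~1),
                               n_iter = 3000, burn = 800, thin = 4,
                               seed = 14), d2)
  p_obs <- mean(vapply(seq_len(fit$n_kept), function(i)
    binary_data_scale_prob(fit$lp_mean[i], fit$vcv$id[i, 1, 1]),
    numeric(1)))
  expect_equal(p_obs, 0.5, tolerance = 0.06)
  expect_equal(mean(d2$y), 0.5, tolerance = 0.05)
})
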