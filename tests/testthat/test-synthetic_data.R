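test_that("roster structure follows the design and is reproducible", {
  d <- sim_design(n_families_per_cross = 3, n_offspring_per_family = 40)
  r <- generate_design(d, seed = 7)
  expect_equal(nrow(r), 3 * 3 * 40)
  expect_equal(anyDuplicated(r$id), 0L)
  # families nested within cross type
  expect_true(all(tapply(as.character(r$cross), r$family,
                         function(x) length(unique(x))) == 1))
  d1 <- sim_design(n_families_per_cross = 1, n_offspring_per_family = 1)
  r1 <- generate_design(d1, seed = 1)
  expect_equal(nrow(r1), 3)
  expect_equal(length(unique(r1$family)), 3)
  expect_identical(generate_design(d, 11), generate_design(d, 11))
  expect_error(sim_design(n_offspring_per_family = 0), "counts")
  expect_error(sim_design(stages = c(1, 2, 2, 3)), "increasing")
  expect_error(sim_design(cross_types = c("a", "b")), "3 distinct")
})

test_that("zero-variance parameters collapse traits onto the cross means", {
  d <- tiny_design()
  p <- shared_cov_params(d, diag(1e-18, 7),
                         family_cov = diag(1e-18, 7),
                         resid_cov = diag(1e-18, 7))
  tt <- simulate_traits(generate_design(d, 1), p, seed = 2)
  w <- traits_wide(tt)
  for (cc in d$cross_types) {
    vals <- as.matrix(w[w$cross == cc, p_traits()])
    expect_equal(vals, matrix(p$cross_means[cc, ], nrow(vals), 7,
                              byrow = TRUE, dimnames = dimnames(vals)),
                 tolerance = 1e-6)
  }
})

test_that("sample covariance converges to the generating covariance", {
  d <- sim_design(n_families_per_cross = 1, n_offspring_per_family = 3400)
  p <- shared_cov_params(d, diag(7))
  tt <- simulate_traits(generate_design(d, 3), p, seed = 4)
  w <- traits_wide(tt)
  for (cc in d$cross_types) {
    S <- cov(as.matrix(w[w$cross == cc, p_traits()]))
    expect_lt(max(abs(S - diag(7))), 0.1)
  }
})

test_that("trait tables differ across seeds but keep the schema", {
  d <- tiny_design()
  p <- sim_params(d)
  r <- generate_design(d, 1)
  a <- simulate_traits(r, p, seed = 1)
  b <- simulate_traits(r, p, seed = 2)
  expect_identical(names(a), names(b))
  expect_identical(dim(a), dim(b))
  expect_false(isTRUE(all.equal(a$value, b$value)))
  expect_error(sim_params(d, resid_cov = matrix(-1, 7, 7)),
               "positive semi-definite")
  bad <- diag(7); bad[1, 1] <- -1
  expect_error(sim_params(d, family_cov = bad), "positive semi-definite")
})

test_that("noise-free landmarks are similarity transforms of the template", {
  d <- tiny_design(1, 4)
  p <- sim_params(d, shape_noise_sd = 0,
                  allometry_vector = rep(0, 40))
  r <- generate_design(d, 1)
  tt <- simulate_traits(r, p, seed = 2)
  lm <- simulate_landmarks(r, tt, p, seed = 3)
  tmpl <- p$shape_template
  for (cfg in lm$configs[1:8]) {
    m <- cfg$coords
    m <- sweep(m, 2, colMeans(m))
    m <- m / sqrt(sum(m^2))
    # optimally rotate back onto the template: residual must vanish
    s <- svd(crossprod(m, tmpl))
    R <- s$u %*% diag(c(1, sign(det(s$u %*% t(s$v))))) %*% t(s$v)
    expect_lt(sqrt(sum((m %*% R - tmpl)^2)), 1e-8)
  }
  # recorded nuisance scale matches the raw centroid size
  cs <- vapply(lm$configs, centroid_size, numeric(1))
  expect_equal(unname(cs), exp(lm$truth$log_csize), tolerance = 1e-8)
  lm2 <- simulate_landmarks(r, tt, p, seed = 3)
  expect_identical(lm$truth, lm2$truth)
})

test_that("behaviour generator matches its latent ground truth", {
  d <- tiny_design()
  p <- sim_params(d, behaviour_latent = data.frame(
    cross = d$cross_types, mean = 0, v_ind = c(0, 1, 0.25),
    v_res = c(1, 1, 0.75)))
  b <- simulate_behaviour(generate_design(d, 1), p, seed = 5)
  expect_equal(unname(b$r_true), c(0, 0.5, 0.25))
  expect_error(
    simulate_behaviour(generate_design(d, 1),
                       sim_params(d, behaviour_latent = data.frame(
                         cross = d$cross_types, mean = 0, v_ind = -1,
                         v_res = 1)), 1),
    "non-negative")
  # probit symmetry: latent mean 0 with unit total variance -> P(fed) ~ 0.5
  d2 <- sim_design(n_families_per_cross = 1, n_offspring_per_family = 3400)
  p2 <- sim_params(d2, behaviour_latent = data.frame(
    cross = d2$cross_types, mean = 0, v_ind = 0.5, v_res = 0.5))
  b2 <- simulate_behaviour(generate_design(d2, 1), p2, seed = 6)
  expect_equal(mean(b2$trials$fed), 0.5, tolerance = 0.02)
})
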