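test_that("noise-free growth curves are recovered essentially exactly", {
  coefs <- rbind(PL = c(3.09, 6.14, -0.70), SB = c(2.98, 5.77, -1.14),
                 F1 = c(2.98, 5.73, -1.00))
  dat <- clean_growth_data(coefs, n_per_cross = 20)
  dat$log_length <- dat$log_length + rnorm(nrow(dat), 0, 1e-6)
  fit <- fit_growth(dat, n_iter = 2500, burn = 500, thin = 4, seed = 1)
  for (cc in rownames(coefs)) {
    co <- fit$coefficients[fit$coefficients$cross == cc, ]
    expect_equal(co$mode[co$term == "intercept"], unname(coefs[cc, 1]),
                 tolerance = 1e-3)
    expect_equal(co$mode[co$term == "slope"], unname(coefs[cc, 2]),
                 tolerance = 1e-3)
    expect_equal(co$mode[co$term == "quadratic"], unname(coefs[cc, 3]),
                 tolerance = 1e-3)
    expect_true(all(co$lo <= co$mode & co$mode <= co$hi))
  }
  # predicted curves increase over the window when slope dominates
  cur <- growth_curves(fit)
  for (cc in rownames(coefs))
    expect_true(all(diff(cur$log_length[cur$cross == cc]) > 0))
  expect_error(fit_growth(transform(dat, standard_length = -1,
                                    log_length = NULL)),
               "non-positive")
})

test_that("identical generating coefficients give overlapping CrIs", {
  coefs <- rbind(PL = c(3, 6, -1), SB = c(3, 6, -1), F1 = c(3, 6, -1))
  set.seed(2)
  dat <- clean_growth_data(coefs, n_per_cross = 25)
  dat$log_length <- dat$log_length + rnorm(nrow(dat), 0, 0.05)
  fit <- fit_growth(dat, n_iter = 2000, burn = 500, thin = 3, seed = 3)
  co <- fit$coefficients
  for (tm in unique(co$term)) {
    sub <- co[co$term == tm, ]
    expect_gt(min(sub$hi), max(sub$lo))  # pairwise overlap of all three
  }
})

test_that("yolk conversion and the yolk model behave as constructed", {
  expect_equal(yolk_conversion(2, 2, 10, 12), 0)
  expect_equal(yolk_conversion(2, 1, 10, 12), 0.25)
  expect_error(yolk_conversion(-1, 1, 10, 12), "negative")
  set.seed(4)
  n <- 360
  id <- sprintf("i%03d", seq_len(n))
  cross <- rep(c("PL", "SB", "F1"), each = n / 3)
  family <- paste0(cross, "_f", rep(1:3, length.out = n))
  log_sl_d1 <- rnorm(n, 2.4, 0.5)
  log_sl_d2 <- log_sl_d1 + rnorm(n, 0.3, 0.05)
  fam_eff <- 0  # a pure null: no cross and no family effects generated
  u <- rnorm(n, 0, 0.15)
  dat <- data.frame(id = id, cross = cross, family = family,
                    yolk_d1 = pmax(0.1, 2.6 + 0.11 * log_sl_d1 + fam_eff +
                                     u + rnorm(n, 0, 0.08)),
                    yolk_d2 = pmax(0.1, 2.5 + 0.11 * log_sl_d2 + fam_eff +
                                     u + rnorm(n, 0, 0.08)),
                    log_sl_d1 = log_sl_d1, log_sl_d2 = log_sl_d2)
  fit <- fit_yolk(dat, n_iter = 2500, burn = 600, thin = 3, seed = 5)
  tab <- fit$table
  cov_rows <- grepl("log\\(standard length", tab$term)
  expect_true(all(tab$mode[cov_rows] > 0.06 & tab$mode[cov_rows] < 0.16))
  # no cross effects were generated: contrasts straddle zero
  ctr <- grepl("Cross type", tab$term)
  expect_true(all(tab$lo[ctr] < 0 & tab$hi[ctr] > 0))
  expect_error(fit_yolk(transform(dat, yolk_d1 = -yolk_d1)), "negative")
})

test_that("onset of feeding extracts first days and censoring", {
  rec <- data.frame(id = rep(c("a", "b"), each = 5),
                    cross = "PL", family = "PL_f1",
                    day = rep(100:104, 2),
                    fed = c(0, 0, 1, 0, 1, 0, 0, 0, 0, 0))
  sp <- split(rec, rec$id)
  first <- do.call(rbind, lapply(sp, function(df) {
    hit <- which(df$fed == 1)
    data.frame(day = if (length(hit)) df$day[hit[1]] else NA)
  }))
  expect_equal(first["a", "day"], 102)
  expect_true(is.na(first["b", "day"]))
  expect_error(onset_of_feeding(transform(rec, fed = fed + 0.5)), "binary")
})

test_that("a constructed five-day onset shift is recovered", {
  set.seed(6)
  d <- sim_design(n_families_per_cross = 3, n_offspring_per_family = 40)
  p <- sim_params(d, onset = list(mean_day = c(PL = 10, SB = 15, F1 = 10),
                                  sd = 3, sd_family = 0.5, p_never = 0.02,
                                  n_days = 30L))
  b <- simulate_behaviour(generate_design(d, 7), p, seed = 8)
  of <- onset_of_feeding(b$onset_records, n_iter = 2500, burn = 500,
                         thin = 3, seed = 9)
  tab <- of$table
  shift <- tab$mode[tab$cross == "SB"] - tab$mode[tab$cross == "PL"]
  expect_equal(shift, 5, tolerance = 1)
  expect_true(any(of$first_feeding$censored))
})

test_that("repeatability follows its defining formula and properties", {
  fake <- function(v_ind, v_res, mu = 0, n = 400) {
    structure(list(vcv = list(id = array(v_ind, c(n, 1, 1))),
                   resid = array(v_res, c(n, 1, 1)),
                   lp_mean = rep(mu, n), n_kept = n),
              class = "posterior_samples")
  }
  r <- repeatability(fake(1, 1), "gaussian")
  expect_equal(r$mode[r$scale == "latent"], 0.5, tolerance = 0.02)
  r0 <- repeatability(fake(0, 1), "gaussian")
  expect_equal(r0$mode[r0$scale == "latent"], 0)
  expect_equal(r0$lo[r0$scale == "latent"], 0)
  expect_error(repeatability(fake(1, 1)[-1], "gaussian"))
  # latent R is invariant to the latent mean; the binary data-scale R is not
  rb1 <- repeatability(fake(0.667, 1, mu = 0), "binary")
  rb2 <- repeatability(fake(0.667, 1, mu = 1.5), "binary")
  expect_equal(rb1$mode[rb1$scale == "latent"],
               rb2$mode[rb2$scale == "latent"], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rb1$mode[rb1$scale == "data"],
                                rb2$mode[rb2$scale == "data"],
                                tolerance = 0.01)))
  # data-scale R below latent R (binary information loss)
  expect_lt(rb1$mode[rb1$scale == "data"], rb1$mode[rb1$scale == "latent"])
})

test_that("quadrature transform matches a large Monte-Carlo oracle", {
  set.seed(10)
  for (case in list(c(0, 0.667), c(0.8, 0.4), c(-0.5, 1.2))) {
    mu <- case[1]; v <- case[2]
    u <- rnorm(1e6, 0, sqrt(v))
    p <- pnorm(mu + u)
    pbar <- mean(p)
    r_mc <- var(p) / (pbar * (1 - pbar))
    expect_equal(binary_data_scale_r(mu, v), r_mc, tolerance = 0.01)
    expect_equal(binary_data_scale_prob(mu, v), pbar, tolerance = 0.005)
  }
})
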