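# Shared fixture builders for the test suite. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

tiny_design <- function(n_fam = 2L, n_off = 6L)
  sim_design(n_families_per_cross = n_fam, n_offspring_per_family = n_off)

# a random symmetric PSD matrix with eigenvalues in (0, scale]
random_psd <- function(q, scale = 1) {
  A <- matrix(rnorm(q * q), q)
  Q <- qr.Q(qr(A))
  Q %*% (runif(q, 0.01, scale) * t(Q))
}

# a random convex polygon (points on a convex curve, ordered by angle)
random_convex_polygon <- function(n) {
  th <- sort(runif(n, 0, 2 * pi))
  r <- runif(1, 0.5, 3)
  cbind(r * cos(th), r * sin(th))
}

# fan-triangulation area oracle, independent of the shoelace implementation
fan_area <- function(pts) {
  n <- nrow(pts)
  a <- 0
  for (i in 2:(n - 1)) {
    v1 <- pts[i, ] - pts[1, ]
    v2 <- pts[i + 1, ] - pts[1, ]
    a <- a + (v1[1] * v2[2] - v1[2] * v2[1]) / 2
  }
  abs(a)
}

# apply a random similarity transform to a k x 2 configuration
random_similarity <- function(m) {
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  s <- runif(1, 0.2, 5)
  sweep(s * m %*% R, 2, runif(2, -10, 10), "+")
}

# params with a single shared covariance for all crosses and no nuisance
# variance; handy for recovery tests
shared_cov_params <- function(design, ind_cov,
                              family_cov = diag(1e-10, 7),
                              resid_cov = diag(1e-10, 7)) {
  sim_params(design, ind_cov = ind_cov, family_cov = family_cov,
             resid_cov = resid_cov)
}

# quick growth fixture: noise-free polynomial curves per cross
clean_growth_data <- function(coefs, n_per_cross = 30L,
                              stages = c(445, 530, 840, 1100)) {
  ts <- (stages - stages[1]) / diff(range(stages))
  crosses <- rownames(coefs)
  do.call(rbind, lapply(crosses, function(cc) {
    do.call(rbind, lapply(seq_len(n_per_cross), function(i) {
      data.frame(id = sprintf("%s_%03d", cc, i), cross = cc,
                 family = paste0(cc, "_f", 1 + (i %% 3)),
                 age = stages, age_scaled = ts,
                 log_length = coefs[cc, 1] + coefs[cc, 2] * ts +
                   coefs[cc, 3] * ts^2)
    }))
  }))
}
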