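test_that("curve resampling is equidistant in arc length", {
  seg <- rbind(c(0, 0), c(1, 0))
  expect_equal(resample_curve(seg, 3), rbind(c(0, 0), c(0.5, 0), c(1, 0)))
  expect_equal(resample_curve(seg, 2), seg)
  # dense half circle: analytic arc length pi, spacing pi/4
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(cos(th), sin(th))
  sl <- resample_curve(semi, 5)
  gaps <- sqrt(rowSums(diff(sl)^2))
  arc <- 2 * asin(gaps / 2)          # chord -> arc on the unit circle
  expect_lt(max(abs(arc - pi / 4)), 1e-3)
  expect_equal(sl[1, ], c(1, 0), tolerance = 1e-9)
  expect_equal(sl[5, ], c(-1, 0), tolerance = 1e-3)
  expect_error(resample_curve(rbind(c(1, 1), c(1, 1)), 3), "degenerate")
  expect_error(resample_curve(rbind(c(0, 0)), 3), ">= 2")
})

test_that("shoelace area matches analytic values and the fan oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1.0)
  expect_equal(polygon_area(sq[4:1, ]), 1.0)  # orientation independent
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6.0)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  expect_equal(polygon_area(cbind(cos(th), sin(th))), pi, tolerance = 1e-3)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), ">= 3")
  set.seed(42)
  for (i in 1:50) {
    poly <- random_convex_polygon(sample(5:40, 1))
    expect_equal(polygon_area(poly), fan_area(poly), tolerance = 1e-10)
  }
})

test_that("standard length is the farthest head semilandmark distance", {
  mk <- function(head_curve, tip) {
    coords <- rbind(notochord_tip = tip, a = c(0, 1), b = c(1, 1))
    landmark_config(coords, id = "x", curves = list(head = head_curve))
  }
  cfg <- mk(rbind(c(0, 0), c(1, 0)), c(10, 0))
  expect_equal(standard_length(cfg), 10.0)
  th <- seq(0, 2 * pi, length.out = 721)
  circ <- cbind(cos(th), sin(th))
  # 50 semilandmarks discretize the circle, so the farthest point (-1, 0)
  # is matched up to the resampling resolution
  expect_equal(standard_length(mk(circ, c(5, 0))), 6.0, tolerance = 5e-3)
  # brute-force oracle on a random polyline
  set.seed(1)
  curve <- cbind(cumsum(runif(30)), rnorm(30))
  tip <- c(-3, 2)
  cfg3 <- mk(curve, tip)
  sl <- resample_curve(curve, 50)
  oracle <- max(sqrt(rowSums(sweep(sl, 2, tip)^2)))
  expect_equal(standard_length(cfg3), oracle)
  expect_error(standard_length(landmark_config(diag(3)[, 1:2] + 1:3,
                                               curves = list())),
               "notochord_tip")
})

test_that("centroid size behaves as the standard size measure", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3 * sq), 3 * sqrt(2))
})

test_that("GPA aligns similarity-transformed copies exactly", {
  tmpl <- default_shape_template()
  set.seed(11)
  configs <- lapply(1:8, function(i) random_similarity(tmpl))
  g <- gpa(configs)
  for (i in 2:8)
    expect_lt(procrustes_distance(g$aligned[, , 1], g$aligned[, , i]), 1e-8)
  # aligned configurations: centred, unit size; consensus = mean shape
  for (i in 1:8) {
    expect_equal(colMeans(g$aligned[, , i]), c(0, 0), tolerance = 1e-9)
    expect_equal(sum(g$aligned[, , i]^2), 1, tolerance = 1e-9)
  }
  cons <- apply(g$aligned, c(1, 2), mean)
  cons <- cons / sqrt(sum(cons^2))
  expect_equal(g$consensus, cons, tolerance = 1e-6)
  expect_equal(procrustes_distance(gpa(list(tmpl, tmpl))$aligned[, , 1],
                                   gpa(list(tmpl, tmpl))$aligned[, , 2]), 0,
               tolerance = 1e-12)
})

test_that("GPA output is invariant to input similarity transforms", {
  set.seed(3)
  base <- lapply(1:10, function(i)
    default_shape_template() + matrix(rnorm(40, 0, 0.01), 20, 2))
  g1 <- gpa(base)
  g2 <- gpa(lapply(base, random_similarity))
  # shapes identical up to a common rotation of the whole aligned set, so
  # all pairwise distances in shape space must match
  A <- shape_matrix(g1); B <- shape_matrix(g2)
  d1 <- as.matrix(dist(A)); d2 <- as.matrix(dist(B))
  expect_equal(d1, d2, tolerance = 1e-8)
  # centroid sizes multiply by the applied scale
  sc <- 2.5
  g3 <- gpa(lapply(base, function(m) m * sc))
  expect_equal(g3$csize, g1$csize * sc, tolerance = 1e-10)
  expect_error(gpa(list(default_shape_template(),
                        default_shape_template()[1:10, ])), "mismatched")
})

test_that("GPA agrees with an independent pairwise Procrustes oracle", {
  skip_if_not_installed("vegan")
  set.seed(8)
  a <- default_shape_template() + matrix(rnorm(40, 0, 0.02), 20, 2)
  b <- default_shape_template() + matrix(rnorm(40, 0, 0.02), 20, 2)
  g <- gpa(list(a, b))
  # vegan's symmetric Procrustes also optimizes a scaling factor (full
  # Procrustes, ss = 1 - cos^2 rho); ours keeps both shapes at unit size
  # (partial, d^2 = 2(1 - cos rho)) -- convert before comparing
  v <- vegan::procrustes(a, b, symmetric = TRUE)
  d2 <- procrustes_distance(g$aligned[, , 1], g$aligned[, , 2])^2
  cos_rho <- 1 - d2 / 2
  expect_equal(v$ss, 1 - cos_rho^2, tolerance = 1e-6)
})
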