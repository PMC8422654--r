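#' Study design for the synthetic common-garden experiment
#'
#' Describes the structure of the rearing experiment the generator emulates:
#' three cross types (two pure-morph crosses and pooled F1 hybrids), full-sib
#' families nested in cross type, offspring reared individually, and four
#' developmental stages on a thermal-age axis (degree-days).
#'
#' @param cross_types character vector of exactly three cross-type labels.
#' @param n_families_per_cross number of full-sib families per cross type.
#' @param n_offspring_per_family number of offspring sampled per family.
#' @param stages four strictly increasing developmental time points in
#'   degree-days (default: hatching, 20 d post-hatching, 3-4 weeks after the
#'   onset of exogenous feeding, 9-11 weeks after onset).
#' @param n_behaviour_trials repeated behavioural observation trials per
#'   individual (default 3).
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(cross_types = c("PL", "SB", "F1"),
                       n_families_per_cross = 3L,
                       n_offspring_per_family = 40L,
                       stages = c(445, 530, 840, 1100),
                       n_behaviour_trials = 3L) {
  if (length(cross_types) != 3L || anyDuplicated(cross_types))
    stop("exactly 3 distinct cross types are required", call. = FALSE)
  if (n_families_per_cross < 1L || n_offspring_per_family < 1L ||
      n_behaviour_trials < 1L)
    stop("all design counts must be >= 1", call. = FALSE)
  if (length(stages) != 4L || any(diff(stages) <= 0))
    stop("'stages' must be 4 strictly increasing time points", call. = FALSE)
  structure(list(cross_types = as.character(cross_types),
                 n_families_per_cross = as.integer(n_families_per_cross),
                 n_offspring_per_family = as.integer(n_offspring_per_family),
                 stages = as.numeric(stages),
                 n_behaviour_trials = as.integer(n_behaviour_trials)),
            class = "sim_design")
}

#' The seven focal traits entering the P matrices
#' @return Character vector of trait names, in the canonical order.
#' @export
p_traits <- function() {
  c("sl_d1", "sl_d3", "growth_d1_d2", "growth_d3_d4",
    "yolk_area_d1", "yolk_conversion", "latency")
}

# Default per-cross trait variances on the mean-standardized scale. The
# first six follow the printed posterior modes of the trait-variance table of
# the charr experiment; the latency variance is a realistic choice of the
# same magnitude.
default_trait_vars <- function() {
  rbind(PL = c(0.14, 0.21, 0.18, 0.31, 0.15, 0.15, 0.15),
        SB = c(0.20, 0.21, 0.22, 0.68, 0.22, 0.21, 0.20),
        F1 = c(0.08, 0.10, 0.13, 0.42, 0.11, 0.12, 0.15))
}

# Modest correlations among the size/growth traits; the study found most
# traits uncorrelated, so the default structure is close to diagonal.
default_trait_cor <- function() {
  r <- diag(7)
  r[1, 2] <- r[2, 1] <- 0.5   # length at hatching ~ length at first feeding
  r[1, 3] <- r[3, 1] <- 0.3
  r[2, 3] <- r[3, 2] <- 0.3
  r
}

cor_to_cov <- function(r, v) diag(sqrt(v)) %*% r %*% diag(sqrt(v))

#' Template head configuration (20 landmarks)
#'
#' Builds the mean head configuration used by the landmark generator: three
#' anatomical landmarks (tip of the lower jaw, lower edge of the maxilla,
#' point of maximum curvature between brain and cranium) plus 13 semilandmarks
#' along the head contour and 4 around the eye. Centred and scaled to unit
#' centroid size.
#' @return A 20 x 2 numeric matrix.
#' @export
default_shape_template <- function() {
  jaw <- c(0, 0)
  maxilla <- c(0.12, -0.06)
  cranium <- c(0.95, 0.30)
  # head contour arc from above the jaw to the cranium point
  t <- seq(0.1, 0.9, length.out = 13)
  head_curve <- cbind(t, 0.42 * sin(pi * t) + 0.05 + 0.25 * t)
  ang <- seq(0, 2 * pi, length.out = 5)[1:4]
  eye <- cbind(0.35 + 0.07 * cos(ang), 0.10 + 0.07 * sin(ang))
  m <- rbind(jaw, maxilla, cranium, head_curve, eye)
  rownames(m) <- c("jaw_tip", "maxilla", "cranium",
                   paste0("head_sl", 1:13), paste0("eye_sl", 1:4))
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

#' Default allometric shape-change vector
#'
#' A smooth displacement field over the template, numerically orthogonalized
#' against translation, rotation and uniform scaling of the template so the
#' injected allometric signal survives Procrustes superimposition, then
#' normalized to length 0.1 (shape change per unit log centroid size).
#'
#' @param template k x 2 landmark template (unit centroid size, centred).
#' @return Numeric vector of length 2k (x-coordinates first, then y).
#' @export
default_allometry <- function(template = default_shape_template()) {
  x <- template[, 1]; y <- template[, 2]
  # raw field: deepen the posterior head, shorten the snout with size
  d <- cbind(-x * abs(x), y * x)
  v <- c(d[, 1], d[, 2])
  k <- nrow(template)
  basis <- cbind(c(rep(1, k), rep(0, k)),        # x-translation
                 c(rep(0, k), rep(1, k)),        # y-translation
                 c(x, y),                        # uniform scaling
                 c(-y, x))                       # infinitesimal rotation
  q <- qr.Q(qr(basis))
  v <- v - q %*% crossprod(q, v)
  0.1 * v / sqrt(sum(v^2))
}

#' Ground-truth parameters for the synthetic generator
#'
#' Houses every quantity the generator needs: per-cross trait means and
#' covariances on the mean-standardized scale, growth-curve polynomial
#' coefficients on the scaled thermal-age axis, latent-scale behaviour
#' parameters, and the landmark model (template, allometry, per-stage sizes).
#' Defaults reproduce the study conditions of the charr experiment: trait
#' variances follow the printed per-cross posterior modes, growth coefficients
#' follow the printed per-cross polynomial estimates, and the behavioural
#' parameters imply the printed feeding-propensity repeatabilities
#' (R about 0.4 in PL x PL, about 0 in the other crosses).
#'
#' @param design a [sim_design()].
#' @param cross_means 3 x 7 matrix of per-cross trait means (rows follow
#'   `design$cross_types`).
#' @param family_cov 7 x 7 family-level covariance (shared across crosses).
#' @param ind_cov a single 7 x 7 matrix or a named list (one per cross) of
#'   individual-level covariances; this is the target P matrix.
#' @param resid_cov 7 x 7 residual (measurement) covariance.
#' @param growth_poly 3 x 3 matrix (rows = crosses) of intercept, slope and
#'   quadratic coefficient of log standard length on thermal age scaled to
#'   `[0, 1]` over the stage window.
#' @param growth_sds named numeric: `family` (random intercept sd), `ind_int`
#'   and `ind_slope` (individual deviations, driven by the individual's trait
#'   deviations so the growth curve covaries with the P traits), `resid`.
#' @param behaviour_latent data frame with one row per cross: `mean`
#'   (latent probit mean of the propensity to start feeding), `v_ind`,
#'   `v_res` (latent individual and trial variances).
#' @param count_params data frame with per-cross `log_mean` and `v_ind` for
#'   the Poisson attack counts.
#' @param zone_probs 3 x 3 matrix of per-cross probabilities of foraging at
#'   the bottom, in the water column, and at the surface.
#' @param onset list: per-cross mean first-feeding day (`mean_day`), between-
#'   individual `sd`, family `sd_family`, probability `p_never` of never
#'   feeding, number of observation days `n_days`.
#' @param shape_template 20 x 2 template configuration.
#' @param allometry_vector length-40 shape change per unit log centroid size.
#' @param shape_noise_sd per-coordinate Gaussian digitizing noise.
#' @param landmark_logsize per-stage mean log centroid size (raw units, mm).
#' @param size_dev_sd sd of the individual log-size deviation (tied to the
#'   individual's standard length at first feeding).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(design = sim_design(),
                       cross_means = NULL,
                       family_cov = NULL,
                       ind_cov = NULL,
                       resid_cov = NULL,
                       growth_poly = NULL,
                       growth_sds = c(family = 0.03, ind_int = 0.05,
                                      ind_slope = 0.15, resid = 0.02),
                       behaviour_latent = NULL,
                       count_params = NULL,
                       zone_probs = NULL,
                       onset = NULL,
                       shape_template = default_shape_template(),
                       allometry_vector = NULL,
                       shape_noise_sd = 0.005,
                       landmark_logsize = log(c(5, 6, 9, 14)),
                       size_dev_sd = 0.1) {
  crosses <- design$cross_types
  traits <- p_traits()
  if (is.null(cross_means)) {
    cross_means <- rbind(c(1, 1, 1, 1, 1, 1, 1),
                         c(0.97, 0.95, 0.92, 0.95, 0.97, 1.00, 1.00),
                         c(0.97, 0.95, 0.92, 0.95, 0.98, 0.95, 1.00))
  }
  cross_means <- as.matrix(cross_means)
  dimnames(cross_means) <- list(crosses, traits)
  if (is.null(family_cov)) family_cov <- diag(0.02, 7)
  if (is.null(resid_cov)) resid_cov <- diag(c(rep(0.005, 6), 0.08))
  if (is.null(ind_cov)) {
    # the published per-cross variances are on the mean-standardized scale;
    # convert to the raw scale with the cross means so that standardizing
    # during the P fit reproduces them
    v <- default_trait_vars()
    r <- default_trait_cor()
    ind_cov <- lapply(seq_along(crosses), function(i) {
      m <- cross_means[i, ]
      diag(m) %*% cor_to_cov(r, v[i, ]) %*% diag(m)
    })
    names(ind_cov) <- crosses
  }
  if (is.matrix(ind_cov)) {
    ind_cov <- setNames(rep(list(ind_cov), 3), crosses)
  }
  if (!all(crosses %in% names(ind_cov)))
    stop("'ind_cov' list must be named by cross type", call. = FALSE)
  check_psd(family_cov, "family_cov")
  check_psd(resid_cov, "resid_cov")
  for (cc in crosses) {
    check_psd(ind_cov[[cc]], paste0("ind_cov[", cc, "]"))
    dimnames(ind_cov[[cc]]) <- list(traits, traits)
  }
  if (is.null(growth_poly)) {
    growth_poly <- rbind(c(3.09, 6.14, -0.70),
                         c(2.98, 5.77, -1.14),
                         c(2.98, 5.73, -1.00))
  }
  growth_poly <- as.matrix(growth_poly)
  dimnames(growth_poly) <- list(crosses, c("intercept", "slope", "quadratic"))
  if (is.null(behaviour_latent)) {
    behaviour_latent <- data.frame(cross = crosses,
                                   mean = c(0.92, 0.54, 0.39),
                                   v_ind = c(0.70, 0.05, 0.05),
                                   v_res = c(1, 1, 1))
  }
  if (any(behaviour_latent$v_ind < 0) || any(behaviour_latent$v_res < 0))
    stop("behaviour latent variances must be non-negative", call. = FALSE)
  if (is.null(count_params)) {
    count_params <- data.frame(cross = crosses,
                               log_mean = c(1.0, 1.3, 1.2),
                               v_ind = c(0.10, 0.30, 0.30))
  }
  if (any(count_params$v_ind < 0))
    stop("count individual variances must be non-negative", call. = FALSE)
  if (is.null(zone_probs)) {
    zone_probs <- rbind(c(0.20, 0.50, 0.30),
                        c(0.60, 0.30, 0.10),
                        c(0.45, 0.40, 0.15))
  }
  zone_probs <- as.matrix(zone_probs)
  dimnames(zone_probs) <- list(crosses, c("bottom", "column", "surface"))
  if (is.null(onset))  # close onset dates, largest mean gap ~5 days
    onset <- list(mean_day = setNames(c(10, 15, 12), crosses),
                  sd = 3, sd_family = 1, p_never = 0.03, n_days = 30L)
  if (nrow(shape_template) != 20L)
    stop("'shape_template' must have 20 landmarks", call. = FALSE)
  if (is.null(allometry_vector)) allometry_vector <- default_allometry(shape_template)
  if (length(allometry_vector) != 2L * nrow(shape_template))
    stop("'allometry_vector' length must be 2 x number of landmarks",
         call. = FALSE)
  structure(list(design = design, cross_means = cross_means,
                 family_cov = family_cov, ind_cov = ind_cov,
                 resid_cov = resid_cov, growth_poly = growth_poly,
                 growth_sds = growth_sds, behaviour_latent = behaviour_latent,
                 count_params = count_params, zone_probs = zone_probs,
                 onset = onset, shape_template = shape_template,
                 allometry_vector = allometry_vector,
                 shape_noise_sd = shape_noise_sd,
                 landmark_logsize = landmark_logsize,
                 size_dev_sd = size_dev_sd),
            class = "sim_params")
}

#' Generate the individual roster
#'
#' @param design a [sim_design()].
#' @param seed integer seed.
#' @return A data frame with one row per individual: `id`, `cross`, `family`.
#' @export
generate_design <- function(design, seed = 1L) {
  if (!inherits(design, "sim_design")) stop("not a sim_design", call. = FALSE)
  with_seed(seed, {
    rows <- do.call(rbind, lapply(design$cross_types, function(cc) {
      fams <- paste0(cc, "_fam", seq_len(design$n_families_per_cross))
      expand.grid(family = fams, off = seq_len(design$n_offspring_per_family),
                  stringsAsFactors = FALSE)
    }))
    cross <- sub("_fam.*$", "", rows$family)
    data.frame(id = sprintf("%s_%02d", rows$family, rows$off),
               cross = factor(cross, levels = design$cross_types),
               family = rows$family, stringsAsFactors = FALSE)
  })
}
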