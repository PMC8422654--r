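#' Simulate the seven focal traits
#'
#' Draws, for every individual, the seven traits entering the P matrices on
#' the mean-standardized scale: trait vector = cross mean + family effect
#' (one draw per family from `family_cov`) + individual effect (from the
#' cross-specific `ind_cov`, the target P) + residual (from `resid_cov`).
#' The latency to start feeding is recorded once per behavioural trial
#' (`n_behaviour_trials` rows, sharing the individual effect but with
#' independent trial residuals).
#'
#' @param roster output of [generate_design()].
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return A long data frame of class `trait_table` with columns `id`,
#'   `cross`, `family`, `stage` (trial index for latency, `NA` otherwise),
#'   `trait`, `value`.
#' @export
simulate_traits <- function(roster, params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  traits <- p_traits()
  ntrial <- params$design$n_behaviour_trials
  with_seed(seed, {
    fams <- unique(roster$family)
    fam_eff <- MASS::mvrnorm(length(fams), rep(0, 7), params$family_cov)
    if (is.null(dim(fam_eff))) fam_eff <- matrix(fam_eff, nrow = 1)
    rownames(fam_eff) <- fams
    n <- nrow(roster)
    ind_eff <- matrix(0, n, 7)
    for (cc in levels(roster$cross)) {
      idx <- which(roster$cross == cc)
      ind_eff[idx, ] <- MASS::mvrnorm(length(idx), rep(0, 7),
                                      params$ind_cov[[cc]])
    }
    resid <- MASS::mvrnorm(n, rep(0, 7), params$resid_cov)
    if (is.null(dim(resid))) resid <- matrix(resid, nrow = 1)
    means <- params$cross_means[as.character(roster$cross), , drop = FALSE]
    vals <- means + fam_eff[roster$family, , drop = FALSE] + ind_eff + resid
    colnames(vals) <- traits
    base <- data.frame(id = rep(roster$id, 6),
                       cross = rep(roster$cross, 6),
                       family = rep(roster$family, 6),
                       stage = NA_integer_,
                       trait = rep(traits[1:6], each = n),
                       value = as.vector(vals[, 1:6]),
                       stringsAsFactors = FALSE)
    # latency: trial 1 uses the joint residual draw, later trials get fresh
    # univariate residuals around the same individual value
    lat_core <- means[, 7] + fam_eff[roster$family, 7] + ind_eff[, 7]
    lat_sd <- sqrt(params$resid_cov[7, 7])
    lat <- lapply(seq_len(ntrial), function(tr) {
      v <- if (tr == 1L) vals[, 7] else lat_core + rnorm(n, 0, lat_sd)
      data.frame(id = roster$id, cross = roster$cross, family = roster$family,
                 stage = tr, trait = "latency", value = v,
                 stringsAsFactors = FALSE)
    })
    out <- rbind(base, do.call(rbind, lat))
    rownames(out) <- NULL
    class(out) <- c("trait_table", "data.frame")
    out
  })
}

#' Trait table in wide, per-individual form
#'
#' Averages repeated latency records per individual and spreads traits to
#' columns; the layout the P-matrix and PLS stages consume.
#'
#' @param traits a `trait_table`.
#' @return Data frame with `id`, `cross`, `family` and one column per trait.
#' @export
traits_wide <- function(traits) {
  agg <- aggregate(value ~ id + cross + family + trait, data = traits,
                   FUN = mean)
  wide <- stats::reshape(agg, idvar = c("id", "cross", "family"),
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[, c("id", "cross", "family", p_traits())]
}

#' Simulate longitudinal growth records
#'
#' Log standard length at each developmental stage follows the per-cross
#' second-order polynomial on thermal age scaled to `[0, 1]`, plus a family
#' random intercept, individual intercept/slope deviations tied to the
#' individual's trait deviations (so growth covaries with the P traits), and
#' measurement noise.
#'
#' @param roster output of [generate_design()].
#' @param traits a `trait_table` from [simulate_traits()] (used to couple the
#'   individual growth deviations to the focal traits).
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return Long data frame: `id`, `cross`, `family`, `age` (degree-days),
#'   `age_scaled`, `log_length`.
#' @export
simulate_growth <- function(roster, traits, params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  stages <- params$design$stages
  ts <- (stages - stages[1]) / diff(range(stages))
  wide <- traits_wide(traits)
  wide <- wide[match(roster$id, wide$id), ]
  mu <- params$cross_means[as.character(roster$cross), , drop = FALSE]
  z1 <- (wide$sl_d1 - mu[, "sl_d1"]) /
    sqrt(sapply(as.character(roster$cross),
                function(cc) params$ind_cov[[cc]]["sl_d1", "sl_d1"]))
  z4 <- (wide$growth_d3_d4 - mu[, "growth_d3_d4"]) /
    sqrt(sapply(as.character(roster$cross),
                function(cc) params$ind_cov[[cc]]["growth_d3_d4", "growth_d3_d4"]))
  sds <- params$growth_sds
  with_seed(seed, {
    fams <- unique(roster$family)
    fam_int <- setNames(rnorm(length(fams), 0, sds["family"]), fams)
    ind_int <- sds["ind_int"] * z1
    ind_slope <- sds["ind_slope"] * z4
    coefs <- params$growth_poly[as.character(roster$cross), , drop = FALSE]
    # realized cohort-mean curve per cross: the generating polynomial plus
    # the mean of the sampled family and individual deviations (with few
    # families the two are only jointly identifiable, so recovery studies
    # target this realized truth)
    realized <- do.call(rbind, lapply(rownames(params$growth_poly),
                                      function(cc) {
      sel <- roster$cross == cc
      fams <- unique(roster$family[sel])
      data.frame(cross = cc,
                 intercept = params$growth_poly[cc, 1] +
                   mean(fam_int[fams]) + mean(ind_int[sel]),
                 slope = params$growth_poly[cc, 2] + mean(ind_slope[sel]),
                 quadratic = params$growth_poly[cc, 3])
    }))
    out <- do.call(rbind, lapply(seq_along(ts), function(s) {
      mu_s <- coefs[, 1] + coefs[, 2] * ts[s] + coefs[, 3] * ts[s]^2
      data.frame(id = roster$id, cross = roster$cross, family = roster$family,
                 age = stages[s], age_scaled = ts[s],
                 log_length = mu_s + fam_int[roster$family] + ind_int +
                   ind_slope * ts[s] + rnorm(nrow(roster), 0, sds["resid"]),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "realized_coefs") <- realized
    out
  })
}

#' Simulate 20-landmark head configurations
#'
#' Each configuration is the template plus the allometric displacement scaled
#' by the individual x stage deviation of log centroid size from its mean,
#' plus iid Gaussian coordinate noise, then randomly rotated, translated and
#' scaled to its raw centroid size (`exp(log size)`). The applied nuisance
#' parameters are returned for testing.
#'
#' @inheritParams simulate_growth
#' @return A list: `configs` (list of [landmark_config()] objects, one per
#'   individual x stage, named `<id>_<stage>`) and `truth` (data frame with
#'   the per-configuration log centroid size and nuisance parameters).
#' @export
simulate_landmarks <- function(roster, traits, params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  template <- params$shape_template
  k <- nrow(template)
  allo <- matrix(params$allometry_vector, ncol = 2)
  wide <- traits_wide(traits)
  wide <- wide[match(roster$id, wide$id), ]
  mu <- params$cross_means[as.character(roster$cross), "sl_d3"]
  z <- (wide$sl_d3 - mu) /
    sqrt(sapply(as.character(roster$cross),
                function(cc) params$ind_cov[[cc]]["sl_d3", "sl_d3"]))
  ls <- params$landmark_logsize
  mean_ls <- mean(ls)
  with_seed(seed, {
    configs <- list()
    truth <- list()
    for (s in seq_along(ls)) {
      lcs <- ls[s] + params$size_dev_sd * z
      for (i in seq_len(nrow(roster))) {
        shp <- template + allo * (lcs[i] - mean_ls) +
          matrix(rnorm(2 * k, 0, params$shape_noise_sd), k, 2)
        th <- runif(1, 0, 2 * pi)
        rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        sc <- exp(lcs[i])
        tr <- runif(2, -10, 10)
        coords <- sweep(sc * shp %*% rot, 2, tr, "+")
        rownames(coords) <- rownames(template)
        nm <- paste0(roster$id[i], "_", s)
        configs[[nm]] <- landmark_config(coords, id = roster$id[i], stage = s)
        truth[[nm]] <- data.frame(id = roster$id[i], stage = s,
                                  log_csize = lcs[i], rotation = th,
                                  scale = sc, tx = tr[1], ty = tr[2])
      }
    }
    list(configs = configs, truth = do.call(rbind, truth))
  })
}

#' Simulate repeated behavioural trials and first-feeding records
#'
#' The propensity to start feeding in a trial comes from a latent Gaussian
#' (per-cross mean + individual effect + trial residual) thresholded at zero
#' (probit scale); attack counts are Poisson on a log link with a log-normal
#' individual effect; the vertical foraging zone is multinomial per cross.
#' Daily one-zero records of first feeding are generated around a per-cross
#' mean onset day; a small fraction of individuals never feed (censored).
#'
#' @param roster output of [generate_design()].
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return A list with `trials` (id, cross, family, trial, fed, attacks,
#'   zone), `onset_records` (daily binary records: id, cross, family, day,
#'   fed), `onset_truth` (true first-feeding day per individual, `NA` if
#'   never feeding) and `r_true` (per-cross true latent-scale repeatability
#'   of the feeding propensity, `v_ind / (v_ind + v_res)`).
#' @export
simulate_behaviour <- function(roster, params, seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (params$design$n_behaviour_trials < 2L)
    stop("at least 2 behavioural trials are required", call. = FALSE)
  bl <- params$behaviour_latent
  cp <- params$count_params
  rownames(bl) <- bl$cross
  rownames(cp) <- cp$cross
  ntrial <- params$design$n_behaviour_trials
  n <- nrow(roster)
  cc <- as.character(roster$cross)
  with_seed(seed, {
    u_feed <- rnorm(n, 0, sqrt(bl[cc, "v_ind"]))
    u_count <- rnorm(n, 0, sqrt(cp[cc, "v_ind"]))
    trials <- do.call(rbind, lapply(seq_len(ntrial), function(tr) {
      latent <- bl[cc, "mean"] + u_feed + rnorm(n, 0, sqrt(bl[cc, "v_res"]))
      fed <- as.integer(latent > 0)
      attacks <- rpois(n, exp(cp[cc, "log_mean"] + u_count)) * fed
      zone <- vapply(cc, function(x)
        sample(colnames(params$zone_probs), 1, prob = params$zone_probs[x, ]),
        character(1))
      data.frame(id = roster$id, cross = roster$cross, family = roster$family,
                 trial = tr, fed = fed, attacks = attacks, zone = zone,
                 stringsAsFactors = FALSE)
    }))
    rownames(trials) <- NULL
    on <- params$onset
    fams <- unique(roster$family)
    fam_eff <- setNames(rnorm(length(fams), 0, on$sd_family), fams)
    never <- runif(n) < on$p_never
    day1 <- pmax(1, round(on$mean_day[cc] + fam_eff[roster$family] +
                            rnorm(n, 0, on$sd)))
    day1[never] <- NA_integer_
    day1[!never & day1 > on$n_days] <- on$n_days
    rec <- expand.grid(day = seq_len(on$n_days), idx = seq_len(n))
    fed_day <- ifelse(is.na(day1[rec$idx]), 0L,
                      ifelse(rec$day < day1[rec$idx], 0L,
                             ifelse(rec$day == day1[rec$idx], 1L,
                                    rbinom(nrow(rec), 1, 0.8))))
    onset_records <- data.frame(id = roster$id[rec$idx],
                                cross = roster$cross[rec$idx],
                                family = roster$family[rec$idx],
                                day = rec$day, fed = fed_day,
                                stringsAsFactors = FALSE)
    r_true <- setNames(bl$v_ind / (bl$v_ind + bl$v_res), bl$cross)
    list(trials = trials, onset_records = onset_records,
         onset_truth = data.frame(id = roster$id, first_day = day1),
         r_true = r_true)
  })
}

#' Run the whole generator
#'
#' Convenience wrapper producing every input the downstream stages consume,
#' with per-component seeds derived from one root seed.
#'
#' @param design a [sim_design()].
#' @param params a [sim_params()].
#' @param seed root integer seed.
#' @return A list: `roster`, `traits`, `growth`, `landmarks`, `behaviour`,
#'   `params`, `seed`.
#' @export
simulate_all <- function(design = sim_design(), params = sim_params(design),
                         seed = 1L) {
  roster <- generate_design(design, stage_seed(seed, "design"))
  traits <- simulate_traits(roster, params, stage_seed(seed, "traits"))
  growth <- simulate_growth(roster, traits, params, stage_seed(seed, "growth"))
  landmarks <- simulate_landmarks(roster, traits, params,
                                  stage_seed(seed, "landmarks"))
  behaviour <- simulate_behaviour(roster, params, stage_seed(seed, "behaviour"))
  list(roster = roster, traits = traits, growth = growth,
       landmarks = landmarks, behaviour = behaviour, params = params,
       seed = seed)
}
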