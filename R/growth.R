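#' Fit per-cross polynomial growth trajectories
#'
#' Second-order polynomial random regression of log standard length on
#' thermal age scaled to `[0, 1]`: per-cross fixed intercept, slope and
#' quadratic coefficient, a family random intercept, and individual random
#' intercepts (plus slopes when every individual has at least three time
#' points).
#'
#' @param data long data frame: `id`, `cross`, `family`, `age` (or
#'   `age_scaled`), and `log_length` (or `standard_length`, which is
#'   log10-transformed; non-positive lengths are an error).
#' @param n_iter,burn,thin,seed chain settings (see [model_spec()]).
#' @return An object of class `growth_fit`: `coefficients` (data frame with
#'   `cross`, `term`, `mode`, `lo`, `hi`), `variances`, `samples` (the
#'   underlying `posterior_samples`), and `age_range`.
#' @export
fit_growth <- function(data, n_iter = 5000L, burn = 1000L, thin = 4L,
                       seed = 1L) {
  if (!"log_length" %in% names(data)) {
    if (!"standard_length" %in% names(data))
      stop("need 'log_length' or 'standard_length'", call. = FALSE)
    if (any(data$standard_length <= 0))
      stop("non-positive standard lengths: log undefined", call. = FALSE)
    data$log_length <- log10(data$standard_length)
  }
  if (!"age_scaled" %in% names(data)) {
    rng <- range(data$age)
    data$age_scaled <- (data$age - rng[1]) / diff(rng)
  }
  data$cross <- factor(data$cross)
  data$t2 <- data$age_scaled^2
  per_id <- table(data$id)
  random <- list(family = ~1,
                 id = if (min(per_id) >= 3L) ~1 + age_scaled else ~1)
  sp <- model_spec("log_length",
                   fixed = ~ 0 + cross + cross:age_scaled + cross:t2,
                   random = random, n_iter = n_iter, burn = burn,
                   thin = thin, seed = seed, store_ranef = TRUE)
  fit <- fit_gaussian(sp, data)
  crosses <- levels(data$cross)
  has_slope <- ncol(fit$ranef$id[1, , , drop = FALSE]) > 0 &&
    dim(fit$ranef$id)[3] > 1L
  # population-averaged per-cross coefficients: the fixed coefficient plus
  # the mean random deviation of that cross's families and individuals
  # (fixed and unconstrained random intercepts are only jointly identified)
  coefs <- do.call(rbind, lapply(crosses, function(cc) {
    fams <- unique(as.character(data$family[data$cross == cc]))
    ids <- unique(as.character(data$id[data$cross == cc]))
    int <- fit$b[, sprintf("cross%s", cc)] +
      rowMeans(fit$ranef$family[, fams, 1, drop = FALSE]) +
      rowMeans(fit$ranef$id[, ids, 1, drop = FALSE])
    slope <- fit$b[, sprintf("cross%s:age_scaled", cc)]
    if (has_slope)
      slope <- slope + rowMeans(fit$ranef$id[, ids, 2, drop = FALSE])
    quad <- fit$b[, sprintf("cross%s:t2", cc)]
    do.call(rbind, lapply(list(list("intercept", int),
                               list("slope", slope),
                               list("quadratic", quad)), function(z) {
      ci <- hpd_interval(z[[2]])
      data.frame(cross = cc, term = z[[1]], mode = posterior_mode(z[[2]]),
                 lo = ci[1], hi = ci[2])
    }))
  }))
  rownames(coefs) <- NULL
  vars <- posterior_summary(fit)
  vars <- vars[grepl("^var\\(", vars$param), ]
  structure(list(coefficients = coefs, variances = vars, samples = fit,
                 age_range = range(data$age)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Per-cross polynomial growth trajectories (scaled thermal age)\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Predicted growth curves from a fitted model
#' @param fit a `growth_fit`.
#' @param n_points grid resolution on the scaled age axis.
#' @return Data frame `cross`, `age`, `age_scaled`, `log_length`.
#' @export
growth_curves <- function(fit, n_points = 50L) {
  t <- seq(0, 1, length.out = n_points)
  co <- fit$coefficients
  do.call(rbind, lapply(unique(co$cross), function(cc) {
    m <- setNames(co$mode[co$cross == cc], co$term[co$cross == cc])
    data.frame(cross = cc,
               age = fit$age_range[1] + t * diff(fit$age_range),
               age_scaled = t,
               log_length = m["intercept"] + m["slope"] * t +
                 m["quadratic"] * t^2)
  }))
}

#' Yolk conversion per unit growth
#'
#' Relative yolk consumed per unit of growth: `(a1 - a2) / (l2 - l1)`
#' normalized by the initial area `a1`. Identical areas give 0.
#'
#' @param area_d1,area_d2 yolk areas at the two stages.
#' @param length_d1,length_d2 standard lengths at the two stages.
#' @return Numeric vector.
#' @export
yolk_conversion <- function(area_d1, area_d2, length_d1, length_d2) {
  if (any(c(area_d1, area_d2) < 0)) stop("negative areas", call. = FALSE)
  dl <- length_d2 - length_d1
  if (any(dl <= 0)) stop("lengths must increase between stages", call. = FALSE)
  (area_d1 - area_d2) / dl / area_d1
}

#' Bivariate yolk-sac model
#'
#' Mixed model of the yolk area at hatching (D1) and 20 days post-hatching
#' (D2), with per-stage intercepts, per-stage log standard-length covariates
#' and per-stage cross contrasts against the first (PL x PL) level, fitted
#' in stacked form with individual and family random intercepts linking the
#' two stages.
#'
#' @param data data frame with `id`, `cross`, `family`, `yolk_d1`,
#'   `yolk_d2`, `log_sl_d1`, `log_sl_d2`.
#' @param n_iter,burn,thin,seed chain settings.
#' @return A list of class `yolk_fit`: `table` (posterior mode and 95% CrI
#'   per fixed effect, shaped like the published yolk-model table) and
#'   `samples`.
#' @export
fit_yolk <- function(data, n_iter = 5000L, burn = 1000L, thin = 4L,
                     seed = 1L) {
  need <- c("id", "cross", "family", "yolk_d1", "yolk_d2",
            "log_sl_d1", "log_sl_d2")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(data$yolk_d1 < 0 | data$yolk_d2 < 0))
    stop("negative yolk areas", call. = FALSE)
  keep <- complete.cases(data[, need])
  data <- data[keep, ]
  long <- rbind(
    data.frame(id = data$id, cross = data$cross, family = data$family,
               stage = "d1", yolk = data$yolk_d1, log_sl = data$log_sl_d1),
    data.frame(id = data$id, cross = data$cross, family = data$family,
               stage = "d2", yolk = data$yolk_d2, log_sl = data$log_sl_d2))
  long$stage <- factor(long$stage)
  long$cross <- factor(long$cross)
  sp <- model_spec("yolk", fixed = ~ 0 + stage + stage:log_sl + stage:cross,
                   random = list(id = ~1, family = ~1),
                   n_iter = n_iter, burn = burn, thin = thin, seed = seed)
  fit <- fit_gaussian(sp, long)
  crosses <- levels(long$cross)
  lab <- c("Response (yolk area at D1)" = "staged1",
           "Response (yolk area at D2)" = "staged2",
           "Yolk area at D1 x log(standard length at D1)" = "staged1:log_sl",
           "Yolk area at D2 x log(standard length at D2)" = "staged2:log_sl")
  for (cc in crosses[-1]) {
    lab[sprintf("Yolk area at D1 x Cross type %s", cc)] <-
      sprintf("staged1:cross%s", cc)
    lab[sprintf("Yolk area at D2 x Cross type %s", cc)] <-
      sprintf("staged2:cross%s", cc)
  }
  tab <- do.call(rbind, lapply(names(lab), function(nm) {
    x <- fit$b[, lab[[nm]]]
    ci <- hpd_interval(x)
    data.frame(term = nm, mode = posterior_mode(x), lo = ci[1], hi = ci[2])
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, samples = fit, baseline = crosses[1]),
            class = "yolk_fit")
}

#' @export
print.yolk_fit <- function(x, ...) {
  cat("Bivariate yolk-sac model (baseline ", x$baseline, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Onset of exogenous feeding from daily one-zero records
#'
#' The onset is the first day an individual is recorded feeding; individuals
#' never observed feeding are flagged censored and excluded from the
#' cross-level Gaussian mixed model of onset day (cross fixed, family
#' random).
#'
#' @param records data frame: `id`, `cross`, `family`, `day`, `fed` (0/1
#'   daily records).
#' @param n_iter,burn,thin,seed chain settings.
#' @return A list of class `onset_fit`: `first_feeding` (per individual:
#'   `day`, `censored`), `table` (per-cross posterior mode and 95% CrI of
#'   the mean onset day), `samples`.
#' @export
onset_of_feeding <- function(records, n_iter = 4000L, burn = 1000L,
                             thin = 3L, seed = 1L) {
  if (!all(records$fed %in% c(0, 1)))
    stop("daily records must be binary", call. = FALSE)
  sp <- split(records, records$id)
  first <- do.call(rbind, lapply(sp, function(df) {
    df <- df[order(df$day), ]
    hit <- which(df$fed == 1)
    data.frame(id = df$id[1], cross = df$cross[1], family = df$family[1],
               day = if (length(hit)) df$day[hit[1]] else NA_integer_,
               censored = length(hit) == 0)
  }))
  rownames(first) <- NULL
  fed <- first[!first$censored, ]
  fed$cross <- factor(fed$cross)
  spm <- model_spec("day", fixed = ~ 0 + cross, random = list(family = ~1),
                    n_iter = n_iter, burn = burn, thin = thin, seed = seed)
  fit <- fit_gaussian(spm, transform(fed, day = as.numeric(day)))
  tab <- do.call(rbind, lapply(levels(fed$cross), function(cc) {
    x <- fit$b[, paste0("cross", cc)]
    ci <- hpd_interval(x)
    data.frame(cross = cc, mode = posterior_mode(x), lo = ci[1], hi = ci[2])
  }))
  rownames(tab) <- NULL
  structure(list(first_feeding = first, table = tab, samples = fit),
            class = "onset_fit")
}

#' @export
print.onset_fit <- function(x, ...) {
  cat(sprintf("Onset of exogenous feeding: %d individuals, %d censored\n",
              nrow(x$first_feeding), sum(x$first_feeding$censored)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
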