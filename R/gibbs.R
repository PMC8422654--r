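#' Specification of a Bayesian linear mixed model
#'
#' Describes a (possibly multi-response) linear mixed model for the Gibbs
#' sampler: responses, fixed-effect formula, random-effect grouping factors
#' (each with a within-group design, default random intercept), the
#' inverse-Wishart prior on each (co)variance component, and chain settings.
#'
#' @param response character vector of response column names (one or more
#'   traits).
#' @param fixed one-sided fixed-effects formula (e.g. `~ cross + log_size`).
#' @param random named list of one-sided formulas; names are grouping
#'   columns, values the within-group design (`~1` for a random intercept,
#'   `~1 + t` for intercept + slope). `NULL` for no random effects.
#' @param prior list with `V` (prior scale, scalar or matrix) and `nu`
#'   (degrees of belief). Defaults follow weakly informative practice:
#'   `V = 1`, `nu = 0.002` for single-response models and `nu` equal to the
#'   number of responses for multi-response models.
#' @param n_iter total MCMC iterations (default 5000).
#' @param burn burn-in iterations discarded (default 1000).
#' @param thin thinning interval (default 4).
#' @param seed chain seed.
#' @param r_fixed optional fixed residual covariance matrix (q x q); used
#'   for latent-probit binary models (fixed to 1) and for multi-response
#'   fits where single-record traits require a pinned residual.
#' @param store_ranef also store the random-effect draws themselves (needed
#'   for population-averaged summaries; off by default to save memory).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = ~1, random = NULL, prior = NULL,
                       n_iter = 5000L, burn = 1000L, thin = 4L, seed = 1L,
                       r_fixed = NULL, store_ranef = FALSE) {
  q <- length(response)
  if (is.null(prior)) prior <- list(V = 1, nu = if (q > 1) q else 0.002)
  if (n_iter <= burn) stop("'n_iter' must exceed 'burn'", call. = FALSE)
  if (!is.null(random)) {
    if (is.null(names(random)) || any(names(random) == ""))
      stop("'random' must be a named list of formulas", call. = FALSE)
  }
  structure(list(response = response, fixed = fixed, random = random,
                 prior = prior, n_iter = as.integer(n_iter),
                 burn = as.integer(burn), thin = as.integer(thin),
                 seed = seed, r_fixed = r_fixed, store_ranef = store_ranef),
            class = "model_spec")
}

# expand prior scale to a d x d matrix
prior_scale <- function(V, d) {
  if (is.matrix(V)) { stopifnot(nrow(V) == d); V } else diag(V, d)
}

draw_invwishart <- function(df, scale) {
  # Sigma^-1 ~ Wishart(df, scale^-1); returns Sigma
  W <- rWishart(1, df, solve(scale))[, , 1]
  solve(0.5 * (W + t(W)))
}

# Core Gibbs sampler. Y n x q, X n x p, rf = list of random-factor
# structures; binary models pass the 0/1 response in Y and binary = TRUE.
gibbs_run <- function(Y, X, rf, prior, n_iter, burn, thin, seed,
                      r_fixed = NULL, binary = FALSE, store_ranef = FALSE) {
  n <- nrow(Y); q <- ncol(Y); p <- ncol(X)
  set.seed(as.integer(seed))
  XtX <- crossprod(X)
  ridge <- diag(1e-8, p * q)
  kept <- floor((n_iter - burn) / thin)
  if (kept < 1L) stop("chain settings store no draws", call. = FALSE)
  # state
  B <- matrix(0, p, q)
  R <- if (!is.null(r_fixed)) r_fixed else diag(apply(Y, 2, var), q)
  if (binary) R <- matrix(1, 1, 1)
  for (f in seq_along(rf)) {
    # dimension of the component: r coefficients for single-response models,
    # q correlated intercepts for multi-response models
    d <- rf[[f]]$d <- if (q == 1L) rf[[f]]$r else q
    rf[[f]]$U <- matrix(0, rf[[f]]$L, d)
    rf[[f]]$G <- diag(1, d)
    if (prior$nu + rf[[f]]$L <= d - 1)
      stop("improper inverse-Wishart posterior: too few levels for prior",
           call. = FALSE)
    rf[[f]]$Vp <- prior_scale(prior$V, d)
  }
  yobs <- Y
  if (binary) Y <- matrix(ifelse(yobs[, 1] == 1, 0.5, -0.5), n, 1)
  out_b <- matrix(NA_real_, kept, p * q)
  out_g <- lapply(rf, function(f) array(NA_real_, c(kept, f$d, f$d)))
  out_r <- array(NA_real_, c(kept, q, q))
  out_lp <- numeric(kept)
  out_u <- if (store_ranef)
    lapply(rf, function(f) array(NA_real_, c(kept, f$L, f$d))) else NULL
  contrib <- function(f) {
    U <- rf[[f]]$U; g <- rf[[f]]$g; W <- rf[[f]]$W; r <- rf[[f]]$r
    if (q == 1L) {
      matrix(rowSums(W * U[g, , drop = FALSE]), n, 1)
    } else {
      # r == 1 in all multi-response models here
      U[g, , drop = FALSE] * W[, 1]
    }
  }
  store_i <- 0L
  for (iter in seq_len(n_iter)) {
    Rinv <- solve(R)
    # --- latent augmentation for binary response
    if (iter > 1L && binary) {
      m <- X %*% B
      for (f in seq_along(rf)) m <- m + contrib(f)
      a <- pnorm(-m)
      u <- runif(n)
      u <- ifelse(yobs[, 1] == 1, a + u * (1 - a), u * a)
      u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
      Y <- m + qnorm(u)
    }
    # --- fixed effects
    Yt <- Y
    for (f in seq_along(rf)) Yt <- Yt - contrib(f)
    Pb <- kronecker(Rinv, XtX) + ridge
    rhs <- as.vector(crossprod(X, Yt %*% Rinv))
    Ub <- chol(Pb)
    m <- backsolve(Ub, forwardsolve(t(Ub), rhs))
    B <- matrix(m + backsolve(Ub, rnorm(p * q)), p, q)
    fit_fix <- X %*% B
    # --- random effects
    for (f in seq_along(rf)) {
      Yt <- Y - fit_fix
      for (f2 in seq_along(rf)) if (f2 != f) Yt <- Yt - contrib(f2)
      st <- rf[[f]]
      Ginv <- solve(st$G)
      if (st$r == 1L) {
        # reorder = TRUE sorts rows by integer level, i.e. 1..L
        Tm <- rowsum(Yt * st$W[, 1], st$g, reorder = TRUE)
        U <- matrix(0, st$L, q)
        for (nb in unique(st$nl)) {
          lev <- which(st$nl == nb)
          Prec <- Ginv + nb * Rinv
          Pinv <- solve(Prec)
          M <- Tm[lev, , drop = FALSE] %*% Rinv %*% Pinv
          U[lev, ] <- M + matrix(rnorm(length(lev) * q), length(lev), q) %*%
            chol(Pinv)
        }
        rf[[f]]$U <- U
      } else if (q == 1L) {
        sigma2 <- R[1, 1]
        A <- rowsum(st$W * Yt[, 1], st$g, reorder = TRUE)
        if (st$balanced) {
          Prec <- Ginv + st$C / sigma2
          Pinv <- solve(Prec)
          M <- (A %*% Pinv) / sigma2
          rf[[f]]$U <- M + matrix(rnorm(st$L * st$r), st$L, st$r) %*% chol(Pinv)
        } else {
          U <- matrix(0, st$L, st$r)
          for (l in seq_len(st$L)) {
            Prec <- Ginv + st$Cl[[l]] / sigma2
            Pinv <- solve(Prec)
            ml <- Pinv %*% (A[l, ] / sigma2)
            U[l, ] <- ml + t(chol(Pinv)) %*% rnorm(st$r)
          }
          rf[[f]]$U <- U
        }
      } else {
        stop("random slopes with multiple responses are not supported",
             call. = FALSE)
      }
      # variance component
      st <- rf[[f]]
      S <- prior$nu * st$Vp + crossprod(rf[[f]]$U)
      rf[[f]]$G <- draw_invwishart(prior$nu + st$L, S)
    }
    # --- residual covariance
    E <- Y - fit_fix
    for (f in seq_along(rf)) E <- E - contrib(f)
    if (is.null(r_fixed) && !binary) {
      S <- prior$nu * prior_scale(prior$V, q) + crossprod(E)
      R <- draw_invwishart(prior$nu + n, S)
    }
    if (iter > burn && (iter - burn) %% thin == 0L) {
      store_i <- store_i + 1L
      out_b[store_i, ] <- as.vector(B)
      for (f in seq_along(rf)) {
        out_g[[f]][store_i, , ] <- rf[[f]]$G
        if (store_ranef) out_u[[f]][store_i, , ] <- rf[[f]]$U
      }
      out_r[store_i, , ] <- R
      out_lp[store_i] <- mean(fit_fix)
    }
  }
  list(b = out_b, g = out_g, r = out_r, lp_mean = out_lp, u = out_u,
       kept = store_i)
}

build_random <- function(random, data) {
  rf <- list()
  for (nm in names(random)) {
    if (!nm %in% names(data))
      stop(sprintf("grouping column '%s' not in data", nm), call. = FALSE)
    g <- droplevels(as.factor(data[[nm]]))
    W <- model.matrix(random[[nm]], data = data)
    r <- ncol(W)
    gi <- as.integer(g)
    Cl <- lapply(seq_len(nlevels(g)), function(l)
      crossprod(W[gi == l, , drop = FALSE]))
    balanced <- all(vapply(Cl, function(m)
      isTRUE(all.equal(m, Cl[[1]], tolerance = 1e-10)), logical(1)))
    rf[[nm]] <- list(name = nm, g = gi, W = W, r = r, L = nlevels(g),
                     d = r * 1L, nl = as.integer(table(gi)),
                     Cl = Cl, C = Cl[[1]], balanced = balanced,
                     levels = levels(g))
  }
  rf
}

#' Fit a Gaussian (multi-response) linear mixed model by Gibbs sampling
#'
#' Gibbs cycle: fixed effects from their multivariate-normal full
#' conditional, random effects likewise, and each (co)variance component
#' from its inverse-Wishart full conditional under the weakly informative
#' prior `(V, nu)`. Rows with missing responses are excluded.
#'
#' @param spec a [model_spec()].
#' @param data data frame holding responses and covariates.
#' @return An object of class `posterior_samples`.
#' @export
fit_gaussian <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(spec$response, names(data))
  if (length(miss)) stop("response column(s) missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  keep <- complete.cases(data[, spec$response, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  Y <- as.matrix(data[, spec$response, drop = FALSE])
  if (any(apply(Y, 2, var) == 0))
    stop("zero-variance response", call. = FALSE)
  X <- model.matrix(spec$fixed, data = data)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design", call. = FALSE)
  q <- ncol(Y)
  if (!is.null(spec$random) && q > 1L) {
    bad <- vapply(spec$random, function(f) ncol(model.matrix(f, data)) > 1L,
                  logical(1))
    if (any(bad))
      stop("multi-response models support random intercepts only",
           call. = FALSE)
  }
  if (spec$prior$nu <= q - 1 && is.null(spec$r_fixed))
    stop("prior 'nu' too small for a proper residual inverse-Wishart",
         call. = FALSE)
  rf <- build_random(spec$random, data)
  raw <- gibbs_run(Y, X, rf, spec$prior, spec$n_iter, spec$burn, spec$thin,
                   spec$seed, r_fixed = spec$r_fixed, binary = FALSE,
                   store_ranef = isTRUE(spec$store_ranef))
  as_posterior(raw, spec, X, rf)
}

#' Fit a binary-response mixed model (latent probit) by Gibbs sampling
#'
#' Albert-Chib latent-variable augmentation: truncated-normal draws of the
#' latent liabilities, followed by the Gaussian cycle, with the residual
#' variance fixed to 1 for identifiability. Variance components are on the
#' latent (liability) scale.
#'
#' @inheritParams fit_gaussian
#' @return An object of class `posterior_samples`.
#' @export
fit_binary <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(spec$response) != 1L)
    stop("binary models take one response", call. = FALSE)
  keep <- complete.cases(data[, spec$response, drop = FALSE])
  data <- data[keep, , drop = FALSE]
  y <- data[[spec$response]]
  if (!all(y %in% c(0, 1)))
    stop("binary response must contain only 0 and 1", call. = FALSE)
  X <- model.matrix(spec$fixed, data = data)
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient fixed-effect design", call. = FALSE)
  rf <- build_random(spec$random, data)
  raw <- gibbs_run(matrix(as.numeric(y), ncol = 1), X, rf, spec$prior,
                   spec$n_iter, spec$burn, spec$thin, spec$seed,
                   r_fixed = matrix(1, 1, 1), binary = TRUE)
  as_posterior(raw, spec, X, rf)
}

as_posterior <- function(raw, spec, X, rf) {
  q <- length(spec$response)
  bn <- if (q == 1L) colnames(X) else
    as.vector(outer(colnames(X), spec$response, function(a, b)
      paste(b, a, sep = ".")))
  colnames(raw$b) <- bn
  vcv <- raw$g
  names(vcv) <- names(rf)
  for (f in seq_along(rf)) {
    dn <- if (rf[[f]]$r == 1L) {
      if (q == 1L) "(Intercept)" else spec$response
    } else colnames(rf[[f]]$W)
    dimnames(vcv[[f]]) <- list(NULL, dn, dn)
  }
  dimnames(raw$r) <- list(NULL, spec$response, spec$response)
  ranef <- raw$u
  if (!is.null(ranef)) {
    names(ranef) <- names(rf)
    for (f in seq_along(rf))
      dimnames(ranef[[f]]) <- list(NULL, rf[[f]]$levels, NULL)
  }
  structure(list(b = raw$b, vcv = vcv, resid = raw$r, lp_mean = raw$lp_mean,
                 ranef = ranef,
                 n_kept = raw$kept, spec = spec,
                 random_levels = lapply(rf, `[[`, "levels"),
                 ess = vapply(seq_len(ncol(raw$b)),
                              function(j) ess(raw$b[, j]), numeric(1))),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d stored draws, %d fixed effect(s), %d random component(s)\n",
              x$n_kept, ncol(x$b), length(x$vcv)))
  print(posterior_summary(x))
  invisible(x)
}

#' Tidy posterior summary (mode and HPD interval per parameter)
#'
#' @param samples a `posterior_samples` object.
#' @param prob HPD mass (default 0.95).
#' @return Data frame with `param`, `mode`, `lo`, `hi`, `ess`.
#' @export
posterior_summary <- function(samples, prob = 0.95) {
  draws <- samples$b
  rows <- lapply(colnames(draws), function(nm) {
    ci <- hpd_interval(draws[, nm], prob)
    data.frame(param = nm, mode = posterior_mode(draws[, nm]),
               lo = ci[1], hi = ci[2],
               ess = samples$ess[match(nm, colnames(draws))])
  })
  vc <- lapply(names(samples$vcv), function(f) {
    arr <- samples$vcv[[f]]
    d <- dim(arr)[2]
    do.call(rbind, lapply(seq_len(d), function(j) {
      x <- arr[, j, j]
      ci <- hpd_interval(x, prob)
      data.frame(param = paste0("var(", f, ":", dimnames(arr)[[2]][j], ")"),
                 mode = posterior_mode(x), lo = ci[1], hi = ci[2],
                 ess = ess(x))
    }))
  })
  res <- lapply(seq_len(dim(samples$resid)[2]), function(j) {
    x <- samples$resid[, j, j]
    ci <- hpd_interval(x, prob)
    data.frame(param = paste0("var(resid:", dimnames(samples$resid)[[2]][j], ")"),
               mode = posterior_mode(x), lo = ci[1], hi = ci[2], ess = ess(x))
  })
  out <- do.call(rbind, c(rows, vc, res))
  rownames(out) <- NULL
  out
}
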