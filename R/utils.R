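#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov density dnorm pnorm qnorm rbinom rnorm rpois
#'   runif sd var model.matrix reformulate rWishart setNames aggregate
#'   complete.cases quantile
#' @importFrom utils read.csv write.csv head
NULL

# Derive a reproducible child seed from a root seed and a stage name.
# Keeps results below 2^31 - 1 so they are valid R integer seeds.
stage_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  r <- abs(root) %% 2147483647
  # all intermediates stay far below 2^53 so no precision is lost
  as.integer(((r * 69621) %% 2147483629 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

is_square_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

check_psd <- function(m, name = "covariance", tol = 1e-8) {
  if (!is_square_symmetric(m, tol))
    stop(sprintf("'%s' must be a symmetric square matrix", name), call. = FALSE)
  ev <- eigen(0.5 * (m + t(m)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev))))
    stop(sprintf("'%s' is not positive semi-definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(m)
}

# Project a symmetric matrix to the PSD cone by clipping negative eigenvalues.
psd_clip <- function(m) {
  e <- eigen(0.5 * (m + t(m)), symmetric = TRUE)
  if (min(e$values) >= 0) return(0.5 * (m + t(m)))
  v <- pmax(e$values, 0)
  e$vectors %*% (v * t(e$vectors))
}

# Effective sample size via Geyer's initial positive sequence estimator.
ess <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10 || var(x) == 0) return(n)
  max_lag <- min(n - 2L, 1000L)
  ac <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                              demean = TRUE)$acf)
  # pair consecutive autocorrelations (Geyer 1992); stop at first negative pair
  s <- 0
  k <- 2L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(1, min(n, n / (1 + 2 * s)))
}
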