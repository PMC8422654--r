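#' Posterior mode of a sample
#'
#' The argmax of a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth; degenerate (constant) samples return the
#' constant.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @return The estimated mode.
#' @export
posterior_mode <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L)
    stop("at least 100 draws are required", call. = FALSE)
  if (var(draws) == 0) return(draws[1])
  d <- density(draws)  # bw.nrd0 is Silverman's rule
  d$x[which.max(d$y)]
}

#' Highest posterior density interval
#'
#' Shortest interval containing the requested posterior mass, found by the
#' sorted-window algorithm.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param prob interval mass (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L)
    stop("at least 100 draws are required", call. = FALSE)
  if (prob <= 0 || prob >= 1) stop("'prob' must be in (0,1)", call. = FALSE)
  s <- sort(draws)
  n <- length(s)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[(m + 1L):n] - s[1:(n - m)]
  j <- which.min(widths)
  c(s[j], s[j + m])
}
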