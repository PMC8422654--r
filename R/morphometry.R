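#' Landmark configuration
#'
#' A single specimen's 2-D landmark configuration, optionally carrying named
#' digitized curves (ordered polylines) from which semilandmarks are
#' extracted.
#'
#' @param coords k x 2 numeric matrix (k >= 3), optionally with landmark
#'   names as row names.
#' @param id specimen identifier.
#' @param stage developmental stage label or index.
#' @param curves named list of m x 2 matrices (ordered polylines).
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(coords, id = NA_character_, stage = NA,
                            curves = list()) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 3L)
    stop("'coords' must be a k x 2 matrix with k >= 3", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (anyDuplicated(round(coords, 12)))
    stop("duplicated landmark coordinates in configuration", call. = FALSE)
  structure(list(id = id, stage = stage, coords = coords, curves = curves),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config '%s' (stage %s): %d landmarks, %d curve(s)\n",
              x$id, as.character(x$stage), nrow(x$coords), length(x$curves)))
  invisible(x)
}

#' Equidistant semilandmarks along a digitized curve
#'
#' Resamples an ordered polyline to `n` points equally spaced in arc length
#' along the piecewise-linear curve; the endpoints are preserved.
#'
#' @param polyline m x 2 matrix of ordered points (m >= 2, nonzero length).
#' @param n number of semilandmarks (>= 2).
#' @return n x 2 matrix of semilandmarks.
#' @export
resample_curve <- function(polyline, n) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs >= 2 points", call. = FALSE)
  if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
  seg <- sqrt(rowSums(diff(polyline)^2))
  L <- c(0, cumsum(seg))
  total <- L[length(L)]
  if (total <= 0) stop("degenerate (zero-length) curve", call. = FALSE)
  keep <- c(TRUE, seg > 0)  # drop repeated points so interpolation is valid
  L <- L[keep]; polyline <- polyline[keep, , drop = FALSE]
  at <- seq(0, total, length.out = n)
  cbind(stats::approx(L, polyline[, 1], xout = at)$y,
        stats::approx(L, polyline[, 2], xout = at)$y)
}

#' Polygon area by the shoelace formula
#'
#' Absolute area of the polygon with the given ordered vertices
#' (orientation-independent; the polygon is closed implicitly).
#'
#' @param points m x 2 matrix of ordered vertices (m >= 3).
#' @return Area in squared input units.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("a polygon needs >= 3 points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the standard size measure of geometric morphometrics.
#'
#' @param coords k x 2 matrix or a [landmark_config()].
#' @return Centroid size in input units.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  cc <- sweep(coords, 2, colMeans(coords))
  sqrt(sum(cc^2))
}

#' Standard length from the notochord tip and the head curve
#'
#' The Euclidean distance between the extremity of the notochord and the
#' farthest of `n` semilandmarks resampled from the head curve.
#'
#' @param config a [landmark_config()] whose `coords` include a landmark
#'   named `notochord_tip` and whose `curves` include `head`.
#' @param n number of head semilandmarks (default 50).
#' @return Length in input units.
#' @export
standard_length <- function(config, n = 50L) {
  stopifnot(inherits(config, "landmark_config"))
  if (!"notochord_tip" %in% rownames(config$coords))
    stop("configuration lacks a 'notochord_tip' landmark", call. = FALSE)
  if (!"head" %in% names(config$curves))
    stop("configuration lacks a 'head' curve", call. = FALSE)
  tip <- config$coords["notochord_tip", ]
  sl <- resample_curve(config$curves[["head"]], n)
  sqrt(max(rowSums(sweep(sl, 2, tip)^2)))
}

# Optimal rotation (no reflection) aligning A onto B, both centred.
kabsch_rotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

as_config_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) return(configs)
  mats <- lapply(configs, function(x)
    if (inherits(x, "landmark_config")) x$coords else as.matrix(x))
  k <- unique(vapply(mats, nrow, 1L))
  if (length(k) != 1L)
    stop("configurations have mismatched landmark counts", call. = FALSE)
  arr <- array(unlist(mats), dim = c(k, 2, length(mats)),
               dimnames = list(rownames(mats[[1]]), NULL, names(mats)))
  arr
}

#' Generalized Procrustes Analysis
#'
#' Superimposes a set of 2-D landmark configurations onto a common coordinate
#' system: each configuration is centred, scaled to unit centroid size, and
#' iteratively rotated (rotation only, no reflection) to the running
#' consensus until the consensus change falls below `tol`.
#'
#' @param configs list of [landmark_config()] objects / k x 2 matrices, or a
#'   k x 2 x n array.
#' @param tol convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter maximum number of alignment sweeps.
#' @return An object of class `procrustes_result`: `aligned` (k x 2 x n
#'   array), `csize` (n raw centroid sizes), `consensus` (k x 2 mean shape),
#'   `iterations`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  arr <- as_config_array(configs)
  n <- dim(arr)[3]
  if (n < 2L) stop("GPA needs >= 2 configurations", call. = FALSE)
  csize <- numeric(n)
  for (i in seq_len(n)) {
    m <- sweep(arr[, , i], 2, colMeans(arr[, , i]))
    csize[i] <- sqrt(sum(m^2))
    if (csize[i] <= 0) stop("degenerate configuration (zero size)", call. = FALSE)
    arr[, , i] <- m / csize[i]
  }
  consensus <- arr[, , 1]
  it <- 0L
  repeat {
    it <- it + 1L
    for (i in seq_len(n)) arr[, , i] <- arr[, , i] %*%
        kabsch_rotation(arr[, , i], consensus)
    new_cons <- apply(arr, c(1, 2), mean)
    new_cons <- sweep(new_cons, 2, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
    if (it >= max_iter)
      stop(sprintf("GPA did not converge in %d iterations (last change %.3g)",
                   max_iter, delta), call. = FALSE)
  }
  names(csize) <- dimnames(arr)[[3]]
  structure(list(aligned = arr, csize = csize, consensus = consensus,
                 iterations = it),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("GPA of %d configurations (%d landmarks), %d iteration(s)\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$iterations))
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#' @param a,b k x 2 matrices.
#' @return Square-root of the summed squared coordinate differences.
#' @export
procrustes_distance <- function(a, b) sqrt(sum((a - b)^2))

#' Flatten aligned configurations to a shape-variable matrix
#' @param x a `procrustes_result` or k x 2 x n array.
#' @return n x 2k matrix (x-coordinates first, then y, per landmark pair
#'   interleaved as x1, y1, x2, y2, ...).
#' @export
shape_matrix <- function(x) {
  arr <- if (inherits(x, "procrustes_result")) x$aligned else x
  k <- dim(arr)[1]; n <- dim(arr)[3]
  out <- t(apply(arr, 3, function(m) as.vector(t(m))))
  colnames(out) <- paste0(rep(c("x", "y"), k), rep(seq_len(k), each = 2))
  rownames(out) <- dimnames(arr)[[3]]
  out
}
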