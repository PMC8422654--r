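#' Read landmark configurations from a TPS file
#'
#' Parses LM, optional CURVES/POINTS, ID and SCALE records. Coordinates
#' (and curve points) are multiplied by SCALE when present. Curves are
#' attached in file order as `curve1`, `curve2`, ... unless renamed later.
#'
#' @param path TPS file path.
#' @return List of [landmark_config()] objects.
#' @export
read_tps <- function(path) {
  lines <- readLines(path)
  configs <- list()
  i <- 1L
  n_lines <- length(lines)
  parse_err <- function(msg, ln) stop(sprintf("TPS parse error at line %d: %s",
                                              ln, msg), call. = FALSE)
  read_coords <- function(start, n, what) {
    if (start + n - 1L > n_lines) parse_err(paste("truncated", what), n_lines)
    m <- matrix(NA_real_, n, 2)
    for (j in seq_len(n)) {
      parts <- suppressWarnings(as.numeric(strsplit(trimws(lines[start + j - 1L]),
                                                    "\\s+")[[1]]))
      if (length(parts) != 2L || anyNA(parts))
        parse_err(paste("expected two numeric coordinates in", what),
                  start + j - 1L)
      m[j, ] <- parts
    }
    m
  }
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE))
      parse_err("expected LM= record", i)
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    if (is.na(k)) parse_err("bad LM count", i)
    coords <- read_coords(i + 1L, k, "landmarks")
    i <- i + 1L + k
    curves <- list()
    while (i <= n_lines && grepl("^CURVES\\s*=", lines[i], ignore.case = TRUE)) {
      nc <- as.integer(sub("^CURVES\\s*=\\s*", "", lines[i], ignore.case = TRUE))
      i <- i + 1L
      for (ci in seq_len(nc)) {
        if (i > n_lines || !grepl("^POINTS\\s*=", lines[i], ignore.case = TRUE))
          parse_err("expected POINTS= record", min(i, n_lines))
        np <- as.integer(sub("^POINTS\\s*=\\s*", "", lines[i],
                             ignore.case = TRUE))
        curves[[paste0("curve", length(curves) + 1L)]] <-
          read_coords(i + 1L, np, "curve points")
        i <- i + 1L + np
      }
    }
    id <- NA_character_
    scale <- NA_real_
    while (i <= n_lines &&
           grepl("^(ID|IMAGE|SCALE)\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE))
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE))
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i],
                                ignore.case = TRUE))
      i <- i + 1L
    }
    if (!is.na(scale)) {
      coords <- coords * scale
      curves <- lapply(curves, function(m) m * scale)
    }
    configs[[length(configs) + 1L]] <-
      landmark_config(coords, id = id, curves = curves)
    if (!is.na(id)) names(configs)[length(configs)] <- id
  }
  configs
}

#' Write landmark configurations to a TPS file
#'
#' @param configs list of [landmark_config()] objects.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_tps <- function(configs, path) {
  out <- character(0)
  fmt <- function(m) apply(m, 1, function(r) sprintf("%.8f %.8f", r[1], r[2]))
  for (cfg in configs) {
    out <- c(out, sprintf("LM=%d", nrow(cfg$coords)), fmt(cfg$coords))
    if (length(cfg$curves)) {
      out <- c(out, sprintf("CURVES=%d", length(cfg$curves)))
      for (cv in cfg$curves)
        out <- c(out, sprintf("POINTS=%d", nrow(cv)), fmt(cv))
    }
    id <- cfg$id
    if (!is.na(cfg$stage) && !is.na(id)) id <- paste0(id, "_", cfg$stage)
    out <- c(out, sprintf("ID=%s", if (is.na(id)) "unknown" else id))
  }
  writeLines(out, path)
  invisible(path)
}
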