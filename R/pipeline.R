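#' Build a pipeline run configuration
#'
#' Either a simulation block (design/params seeds) or paths to existing
#' inputs (traits CSV and landmarks TPS) must be supplied. All randomness
#' downstream flows from `seed`, split per stage by name, so toggling one
#' stage never perturbs another.
#'
#' @param out_dir output directory.
#' @param seed root seed (mandatory when simulating).
#' @param stages stages to run, in dependency order, among `"simulate"`,
#'   `"morpho"`, `"fit"`, `"pmatrix"`, `"pls"`.
#' @param design a [sim_design()] (used when simulating).
#' @param params a [sim_params()] or NULL for defaults.
#' @param traits_csv,landmarks_tps input paths (alternative to simulating).
#' @param n_iter,burn,thin chain settings shared by the model stages.
#' @param n_perm permutations for the resampling tests.
#' @param k common-subspace dimension.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = NULL,
                       stages = c("simulate", "morpho", "fit", "pmatrix",
                                  "pls"),
                       design = sim_design(), params = NULL,
                       traits_csv = NULL, landmarks_tps = NULL,
                       n_iter = 3000L, burn = 800L, thin = 2L,
                       n_perm = 499L, k = 3L) {
  stages <- match.arg(stages, several.ok = TRUE)
  simulating <- "simulate" %in% stages
  if (!simulating && (is.null(traits_csv) || is.null(landmarks_tps)))
    stop("provide input paths or include the 'simulate' stage", call. = FALSE)
  if (simulating && is.null(seed))
    stop("a seed is mandatory when simulating", call. = FALSE)
  if (is.null(params)) params <- sim_params(design)
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 design = design, params = params, traits_csv = traits_csv,
                 landmarks_tps = landmarks_tps, n_iter = n_iter, burn = burn,
                 thin = thin, n_perm = n_perm, k = k),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Mirrors the [run_config()] fields; the `design` block maps onto
#' [sim_design()] arguments.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) do.call(sim_design, y$design) else
    sim_design()
  args <- y[setdiff(names(y), "design")]
  args$design <- design
  do.call(run_config, args)
}

pipe_log <- function(state, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"), level, msg)
  cat(line, "\n", sep = "")
  cat(line, "\n", sep = "", file = state$log_path, append = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate/read -> morphometry -> mixed models -> P matrices / PLS),
#' writing each stage's tables under `out_dir` together with a JSON
#' manifest (seeds, package version, output checksums) and a log. Reruns
#' with the same configuration and seed are byte-identical for the
#' deterministic stages.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(config$out_dir, "pipeline.log"))
  if (file.exists(state$log_path)) unlink(state$log_path)
  outputs <- character(0)
  results <- list()
  seed <- config$seed
  wr <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  # ---- inputs
  if ("simulate" %in% config$stages) {
    pipe_log(state, "INFO", "simulate: generating synthetic dataset")
    sim <- simulate_all(config$design, config$params, seed)
    wr(sim$traits, "traits.csv")
    wr(sim$growth, "growth.csv")
    wr(sim$behaviour$trials, "behaviour_trials.csv")
    wr(sim$behaviour$onset_records, "onset_records.csv")
    tps <- file.path(config$out_dir, "landmarks.tps")
    write_tps(sim$landmarks$configs, tps)
    outputs <- c(outputs, tps)
    yml <- file.path(config$out_dir, "ground_truth.yaml")
    yaml::write_yaml(list(seed = seed,
                          growth_poly = as.list(as.data.frame(t(config$params$growth_poly))),
                          r_true = as.list(sim$behaviour$r_true)), yml)
    outputs <- c(outputs, yml)
    results$sim <- sim
  } else {
    pipe_log(state, "INFO", "read: loading provided inputs")
    traits <- read.csv(config$traits_csv)
    class(traits) <- c("trait_table", "data.frame")
    results$sim <- list(traits = traits,
                        landmarks = list(configs = read_tps(config$landmarks_tps)))
  }
  sim <- results$sim
  # ---- morphometry
  if ("morpho" %in% config$stages) {
    if (is.null(sim$landmarks))
      stop("morpho stage needs landmarks from simulate/read", call. = FALSE)
    pipe_log(state, "INFO", "morpho: GPA, disparity, RRPP, trajectories")
    gp <- gpa(sim$landmarks$configs)
    Y <- shape_matrix(gp)
    meta <- data.frame(name = rownames(Y))
    meta$id <- sub("_[0-9]+$", "", meta$name)
    meta$stage <- as.integer(sub("^.*_", "", meta$name))
    ros <- if (!is.null(sim$roster)) sim$roster else
      unique(sim$traits[, c("id", "cross", "family")])
    meta <- merge(meta, ros, by = "id", sort = FALSE)
    meta <- meta[match(rownames(Y), meta$name), ]
    meta$log_size <- log10(gp$csize[meta$name])
    sseed <- stage_seed(seed, "morpho")
    rr <- rrpp_regression(Y, meta,
                          terms = c("log_size", "cross", "stage",
                                    "cross:family"),
                          n_perm = config$n_perm, seed = sseed)
    wr(as.data.frame(rr), "rrpp_table.csv")
    d3 <- meta$stage == 3
    if (sum(d3) >= 6) {
      dt <- disparity_test(Y[d3, ], meta$cross[d3], n_perm = config$n_perm,
                           seed = sseed + 1L)
      wr(dt$pairwise, "disparity.csv")
      results$disparity <- dt
    }
    tj <- trajectory_analysis(Y, meta$cross, meta$stage,
                              n_perm = config$n_perm, seed = sseed + 2L)
    wr(tj$pairwise, "trajectories.csv")
    results$gpa <- gp
    results$meta <- meta
    results$rrpp <- rr
    results$trajectories <- tj
  }
  # ---- individual-trait models
  if ("fit" %in% config$stages) {
    pipe_log(state, "INFO", "fit: growth, yolk, onset, repeatability")
    fseed <- stage_seed(seed, "fit")
    gf <- fit_growth(sim$growth, n_iter = config$n_iter, burn = config$burn,
                     thin = config$thin, seed = fseed)
    wr(gf$coefficients, "growth_coefficients.csv")
    wide <- traits_wide(sim$traits)
    yd <- make_yolk_data(sim)
    yf <- fit_yolk(yd, n_iter = config$n_iter, burn = config$burn,
                   thin = config$thin, seed = fseed + 1L)
    wr(yf$table, "yolk_table.csv")
    of <- onset_of_feeding(sim$behaviour$onset_records,
                           n_iter = config$n_iter, burn = config$burn,
                           thin = max(1L, config$thin), seed = fseed + 2L)
    wr(of$table, "onset_table.csv")
    reps <- list()
    for (cc in levels(factor(wide$cross))) {
      tr <- sim$behaviour$trials
      tr <- tr[tr$cross == cc, ]
      spb <- model_spec("fed", ~1, random = list(id = ~1),
                        n_iter = config$n_iter, burn = config$burn,
                        thin = config$thin, seed = fseed + 10L)
      fb <- fit_binary(spb, tr)
      rp <- repeatability(fb, "binary")
      rp$cross <- cc
      reps[[cc]] <- rp
    }
    rep_tab <- do.call(rbind, reps)
    wr(rep_tab, "repeatability.csv")
    results$growth_fit <- gf
    results$yolk_fit <- yf
    results$onset_fit <- of
    results$repeatability <- rep_tab
  }
  # ---- P matrices
  if ("pmatrix" %in% config$stages) {
    pipe_log(state, "INFO", "pmatrix: per-cross P, summaries, subspaces")
    pseed <- stage_seed(seed, "pmatrix")
    wide <- traits_wide(sim$traits)
    crosses <- levels(factor(wide$cross))
    Ps <- lapply(crosses, function(cc)
      fit_pmatrix(sim$traits, cc, n_iter = config$n_iter,
                  burn = config$burn, thin = config$thin, seed = pseed))
    names(Ps) <- crosses
    for (p in Ps) if (p$n_clipped > 0)
      pipe_log(state, "WARNING",
               sprintf("pmatrix: %d draws clipped to PSD for %s",
                       p$n_clipped, p$cross))
    summ <- do.call(rbind, lapply(crosses, function(cc) {
      s <- pmatrix_summary(Ps[[cc]])
      s$cross <- cc
      s
    }))
    # per-trait variance table (mode + 80% CrI), one column block per cross
    var_tab <- do.call(rbind, lapply(p_traits(), function(t) {
      j <- match(t, Ps[[1]]$traits)
      row <- data.frame(trait = t)
      for (cc in crosses) {
        x <- Ps[[cc]]$draws[, j, j]
        ci <- hpd_interval(x, 0.80)
        row[[paste0(cc, "_mode")]] <- posterior_mode(x)
        row[[paste0(cc, "_lo")]] <- ci[1]
        row[[paste0(cc, "_hi")]] <- ci[2]
      }
      row
    }))
    wr(var_tab, "trait_variances.csv")
    # pairwise angles with resampling nulls
    cmb <- utils::combn(crosses, 2)
    ang <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1, j]; b <- cmb[2, j]
      s <- pmatrix_summary(Ps[[a]], Ps[[b]])
      s <- s[s$stat == "theta", ]
      nul <- random_angle_null(wide[wide$cross %in% c(a, b), ],
                               leading_eigenvectors(Ps[[a]]),
                               n_rep = config$n_perm, seed = pseed + j)
      data.frame(cross1 = a, cross2 = b, mode = s$mode, lo = s$lo,
                 hi = s$hi, null_lo = nul$ci[1], null_hi = nul$ci[2])
    }))
    wr(ang, "angles.csv")
    H <- krzanowski_H(Ps, k = config$k)
    nullH <- subspace_null(wide, k = config$k, n_rep = config$n_perm,
                           seed = pseed + 50L)
    htab <- H$summary
    htab$null_lo <- nullH$ci[, 1]
    htab$null_hi <- nullH$ci[, 2]
    wr(htab, "subspace_eigenvalues.csv")
    ell <- project_ellipsoids(Ps, reference = crosses[1])
    ell_json <- file.path(config$out_dir, "ellipsoids.json")
    jsonlite::write_json(lapply(ell, function(e)
      list(cross = e$cross, captured = e$captured,
           axes_lengths = e$axes_lengths)), ell_json, auto_unbox = TRUE,
      digits = NA)
    outputs <- c(outputs, ell_json)
    summ_p <- wr(summ, "pmatrix_summary.csv")
    results$P <- Ps
    results$pmatrix_summary <- summ
    results$angles <- ang
    results$subspace <- H
    results$subspace_null <- nullH
    results$ellipsoids <- ell
  }
  # ---- PLS
  if ("pls" %in% config$stages) {
    if (is.null(results$gpa))
      stop("pls stage needs the morpho stage upstream", call. = FALSE)
    pipe_log(state, "INFO", "pls: shape vs trait covariation per cross")
    lseed <- stage_seed(seed, "pls")
    pls_res <- pls_by_cross(traits_wide(sim$traits), results$gpa,
                            results$meta, stage = 3L,
                            n_perm = config$n_perm, seed = lseed)
    wr(pls_res$loadings, "pls_loadings.csv")
    wr(pls_res$comparison, "pls_comparison.csv")
    results$pls <- pls_res
  }
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("charrdiv")),
                   stages = config$stages,
                   outputs = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipe_log(state, "INFO", "done")
  invisible(c(results, list(manifest = manifest)))
}

#' Assemble the yolk-model input from a simulated dataset
#'
#' Maps the mean-standardized yolk-area trait onto a raw-areas layout
#' (areas in mm^2 at hatching and 20 days post-hatching, log standard
#' lengths at the two stages) so the yolk model can run on generator
#' output. The areas carry an explicit log-length allometric component with
#' the stated coefficient (0.11 mm^2 per unit log length, the study's
#' posterior mode), individual variation from the yolk-area trait, and
#' resorption tied to the conversion trait.
#'
#' @param sim output of [simulate_all()] (needs `traits` and `growth`).
#' @param base_area typical yolk area at hatching in mm^2.
#' @param sl_coef allometric coefficient of area on log standard length.
#' @return Data frame for [fit_yolk()].
#' @export
make_yolk_data <- function(sim, base_area = 3, sl_coef = 0.11) {
  wide <- traits_wide(sim$traits)
  gr <- sim$growth
  d1 <- gr[gr$age == min(gr$age), ]
  d2 <- gr[gr$age == sort(unique(gr$age))[2], ]
  log_sl_d1 <- d1$log_length[match(wide$id, d1$id)]
  log_sl_d2 <- d2$log_length[match(wide$id, d2$id)]
  core <- base_area * (wide$yolk_area_d1 - 1)  # individual deviation
  # resorption tied to the conversion trait, around 60% of the D1 area
  resorb <- pmin(0.95, pmax(0.2, 0.6 * wide$yolk_conversion))
  yolk_d1 <- pmax(0.05, base_area + core +
                    sl_coef * (log_sl_d1 - mean(log_sl_d1)))
  yolk_d2 <- pmax(0.05, (base_area + core) * (1 - resorb) +
                    sl_coef * (log_sl_d2 - mean(log_sl_d2)))
  data.frame(id = wide$id, cross = wide$cross, family = wide$family,
             yolk_d1 = yolk_d1, yolk_d2 = yolk_d2,
             log_sl_d1 = log_sl_d1, log_sl_d2 = log_sl_d2)
}

#' Per-cross 2B-PLS of head shape against the P-matrix traits
#'
#' For each cross, pairs the stage-3 aligned head shapes with the
#' individual's seven focal traits (latency averaged over trials), runs the
#' 2B-PLS with its permutation test, and assembles the first-block loading
#' table and the pairwise effect-size comparison matrix.
#'
#' @param wide wide per-individual trait data ([traits_wide()]).
#' @param gp a `procrustes_result` over all configurations.
#' @param meta data frame aligning rows of the shape matrix with `id`,
#'   `cross`, `stage` (as built by the pipeline).
#' @param stage which developmental stage's shapes to use (default 3, the
#'   onset of exogenous feeding).
#' @param n_perm,seed permutation settings.
#' @return A list: `fits` (named `pls_result`s), `loadings` (trait x cross
#'   table of first-block loadings), `comparison` (pairwise two-sample Z
#'   and p), `summary` (per-cross r, p, Z).
#' @export
pls_by_cross <- function(wide, gp, meta, stage = 3L, n_perm = 999L,
                         seed = NULL) {
  Y <- shape_matrix(gp)
  sel <- meta$stage == stage
  crosses <- levels(factor(wide$cross))
  fits <- list()
  for (j in seq_along(crosses)) {
    cc <- crosses[j]
    rows <- which(sel & meta$cross == cc)
    ids <- meta$id[rows]
    X <- as.matrix(wide[match(ids, wide$id), p_traits()])
    fit <- two_block_pls(X, Y[rows, , drop = FALSE])
    fits[[cc]] <- pls_permutation(fit, n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else
                                    seed + j)
  }
  loadings <- data.frame(trait = p_traits())
  for (cc in crosses) loadings[[cc]] <- fits[[cc]]$u
  cmb <- utils::combn(crosses, 2)
  comparison <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    cp <- compare_pls(fits[[cmb[1, j]]], fits[[cmb[2, j]]])
    data.frame(cross1 = cmb[1, j], cross2 = cmb[2, j], Z = cp$Z, p = cp$p)
  }))
  summary <- data.frame(cross = crosses,
                        r = vapply(fits, `[[`, numeric(1), "r"),
                        p = vapply(fits, `[[`, numeric(1), "p"),
                        Z = vapply(fits, `[[`, numeric(1), "Z"))
  rownames(summary) <- NULL
  list(fits = fits, loadings = loadings, comparison = comparison,
       summary = summary)
}
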