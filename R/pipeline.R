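#' Read tracking data from CSV
#'
#' Movebank-style export: one row per fix with columns `id`, `timestamp`
#' (ISO 8601 UTC or numeric seconds), `x`, `y` (planar meters), and
#' optionally `phase` and `year`. Fixes are sorted per individual;
#' duplicate (id, timestamp) pairs are an error.
#'
#' @param path CSV file.
#' @return Named list of track data.frames (one per individual) with
#'   columns `id`, `t` (numeric seconds), `x`, `y` and any optional labels.
#' @export
read_tracks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "timestamp", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("tracks file lacks required column(s): ", paste(miss, collapse = ", "))
  tt <- suppressWarnings(as.numeric(df$timestamp))
  if (any(is.na(tt))) {
    parsed <- rep(NA_real_, nrow(df))
    for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                  "%Y-%m-%d %H:%M:%S")) {
      need <- is.na(parsed)
      if (!any(need)) break
      p <- as.POSIXct(strptime(df$timestamp[need], fmt, tz = "UTC"))
      parsed[need] <- as.numeric(p)
    }
    bad <- which(is.na(parsed))
    if (length(bad))
      stop("unparseable timestamp at data row(s): ",
           paste(head(bad, 5), collapse = ", "))
    tt <- parsed
  }
  df$t <- tt
  key <- paste(df$id, df$t)
  if (anyDuplicated(key))
    stop("duplicated (id, timestamp) pair(s): ",
         paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))
  df <- df[order(df$id, df$t), , drop = FALSE]
  keep <- intersect(c("id", "t", "x", "y", "phase", "year"), names(df))
  lapply(split(df[, keep, drop = FALSE], df$id), function(d) {
    rownames(d) <- NULL
    d
  })
}

#' Write tracks to CSV
#'
#' @param tracks A track data.frame or list of them (columns `id`, `t`,
#'   `x`, `y`, optionally `phase`, `year`).
#' @param path Output CSV; timestamps are written as ISO 8601 UTC.
#' @export
write_tracks <- function(tracks, path) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  df <- do.call(rbind, lapply(tracks, function(d) d[, intersect(
    c("id", "t", "x", "y", "phase", "year"), names(d)), drop = FALSE]))
  df$timestamp <- format(as.POSIXct(df$t, tz = "UTC", origin = "1970-01-01"),
                         "%Y-%m-%dT%H:%M:%SZ")
  df$t <- NULL
  write.csv(df[, c("id", "timestamp", setdiff(names(df),
                                              c("id", "timestamp")))],
            path, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all stage products.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param ... Overrides of the defaults.
#' @return A `RunConfig`-style list.
#' @export
pipeline_config <- function(out_dir, seed, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    # synthetic generation
    n_individuals = 12, n_rows = 120, n_cols = 120, cell_size = 100,
    spacing_min = 2000,
    steps_prospect = 200, steps_settle = 120, n_years_prospect = 2,
    beta_dissim_mean = -0.8, beta_dissim_sd = 0.5,
    beta_dist_mean = -0.05, beta_dist_sd = 0.02,
    step_rate = 1 / 800, n_candidates = 300,
    # analysis parameters
    buffer_radius = 2000, n_avail = 10, resample_interval = 3600,
    resample_tolerance = 900, vmax = 35, k_retained = 2, k_clusters = "auto",
    n_sim = 1000, cv_folds = 5,
    # real-data inputs (NULL = synthetic mode)
    tracks_path = NULL, nests_path = NULL,
    elevation_path = NULL, cover_path = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full NHPI pipeline
#'
#' Orchestrates every stage in order: landscape and nests (generated in
#' synthetic mode, read from disk otherwise), natal habitat assignment
#' (buffer composition, scaled PCA, furthest-neighbour clustering), track
#' acquisition (simulated under a known step-selection process, or read and
#' regularized), the pooled step-length distribution, the matched
#' used/available designs, per-individual-year conditional logistic fits,
#' phase- and year-interaction fits where the labels support them, the
#' NHPI variation metrics with simulated uncertainty, and k-fold
#' cross-validation. All tabular outputs are CSV, model objects JSON, and a
#' run manifest records configuration, seeds and per-stage record counts.
#' Reruns with the same configuration and master seed are bit-identical.
#'
#' @param config A [pipeline_config()] list.
#' @return The run manifest (invisibly also written to
#'   `out_dir/manifest.json`), with all stage outputs attached.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  for (p in c("tracks_path", "nests_path", "elevation_path", "cover_path"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("configured path does not exist: ", p, " = ", cfg[[p]])
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  synthetic <- is.null(cfg$tracks_path)
  counts <- list()

  # --- landscape + nests ---------------------------------------------------
  if (is.null(cfg$elevation_path)) {
    landscape <- generate_landscape(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
                                    cell_size = cfg$cell_size,
                                    seed = derive_seed(cfg$seed, "landscape"))
  } else {
    landscape <- read_raster(cfg$elevation_path, cfg$cover_path)
  }
  write_raster(landscape, file.path(cfg$out_dir, "elevation.asc"),
               file.path(cfg$out_dir, "land_cover.asc"))
  nests <- if (is.null(cfg$nests_path)) {
    place_nests(landscape, cfg$n_individuals, spacing_min = cfg$spacing_min,
                edge_buffer = cfg$buffer_radius,
                seed = derive_seed(cfg$seed, "nests"))
  } else read.csv(cfg$nests_path, stringsAsFactors = FALSE)
  write.csv(nests, file.path(cfg$out_dir, "nests.csv"), row.names = FALSE)
  counts$n_individuals <- nrow(nests)

  # --- natal habitats ------------------------------------------------------
  natal <- assign_natal_habitats(landscape, nests,
                                 radius = cfg$buffer_radius,
                                 k = cfg$k_clusters,
                                 k_retained = cfg$k_retained)
  write.csv(natal$assignment, file.path(cfg$out_dir, "natal_assignment.csv"),
            row.names = FALSE)
  write_pca_json(natal$pca, file.path(cfg$out_dir, "pca_model.json"))
  counts$n_natal_clusters <- natal$clustering$k

  # --- tracks --------------------------------------------------------------
  if (synthetic) {
    set.seed(derive_seed(cfg$seed, "betas"))
    betas <- data.frame(
      id = nests$id,
      beta_dissim = rnorm(nrow(nests), cfg$beta_dissim_mean,
                          cfg$beta_dissim_sd),
      beta_dist = rnorm(nrow(nests), cfg$beta_dist_mean, cfg$beta_dist_sd),
      stringsAsFactors = FALSE)
    write.csv(betas, file.path(cfg$out_dir, "true_coefficients.csv"),
              row.names = FALSE)
    tracks <- lapply(seq_len(nrow(nests)), function(i) {
      segs <- rbind(
        data.frame(phase = "p", year = seq_len(cfg$n_years_prospect),
                   n_steps = cfg$steps_prospect),
        data.frame(phase = "s", year = cfg$n_years_prospect + 1L,
                   n_steps = cfg$steps_settle))
      ind <- list(id = nests$id[i], nest = c(nests$x[i], nests$y[i]),
                  beta_dissim = betas$beta_dissim[i],
                  beta_dist = betas$beta_dist[i], segments = segs)
      simulate_track(landscape, natal$pca, ind, step_rate = cfg$step_rate,
                     n_candidates = cfg$n_candidates,
                     seed = derive_seed(cfg$seed, "track", i),
                     radius = cfg$buffer_radius)
    })
    names(tracks) <- nests$id
  } else {
    tracks <- read_tracks(cfg$tracks_path)
    tracks <- lapply(tracks, function(tr) {
      tr <- resample_track(tr, interval = cfg$resample_interval,
                           tolerance = cfg$resample_tolerance)
      if (isFALSE(attr(tr, "usable"))) return(NULL)
      speed_filter(tr, vmax = cfg$vmax)
    })
    tracks <- Filter(Negate(is.null), tracks)
  }
  write_tracks(tracks, file.path(cfg$out_dir, "tracks.csv"))
  counts$n_tracks <- length(tracks)
  counts$n_fixes <- sum(vapply(tracks, nrow, 0L))

  # --- steps + designs -----------------------------------------------------
  steps <- lapply(tracks, build_steps)
  rate <- fit_step_length_distribution(
    unlist(lapply(steps, `[[`, "length")))
  designs <- list()
  for (id in names(steps)) {
    i <- match(id, nests$id)
    nsc <- natal$pca$scores[i, ]
    designs[[id]] <- build_design(
      steps[[id]], landscape, natal$pca, nsc,
      nest = c(nests$x[i], nests$y[i]), n_avail = cfg$n_avail, rate = rate,
      seed = derive_seed(cfg$seed, "design", i),
      radius = cfg$buffer_radius, drop_oob = !synthetic)
  }
  all_design <- do.call(rbind, designs)
  write.csv(all_design, file.path(cfg$out_dir, "design.csv"),
            row.names = FALSE)
  counts$n_strata <- length(unique(paste(all_design$id, all_design$stratum)))
  counts$n_design_rows <- nrow(all_design)

  # --- per individual-year fits -------------------------------------------
  coef_rows <- list()
  for (id in names(designs)) {
    rec <- fit_individual_years(designs[[id]])
    rec <- cbind(id = id, rec, stringsAsFactors = FALSE)
    coef_rows[[id]] <- rec
  }
  coefs <- do.call(rbind, coef_rows)
  coefs$cluster <- natal$assignment$cluster[match(coefs$id,
                                                  natal$assignment$id)]
  rownames(coefs) <- NULL
  write.csv(coefs, file.path(cfg$out_dir, "coefficients.csv"),
            row.names = FALSE)
  counts$n_models <- nrow(coefs)
  counts$n_converged <- sum(coefs$converged)

  # --- phase / year interaction fits --------------------------------------
  phase_rows <- year_rows <- list()
  for (id in names(designs)) {
    d <- designs[[id]]
    if (all(c("p", "s") %in% d$phase)) {
      yp <- max(d$year[d$phase == "p"]); ysn <- min(d$year[d$phase == "s"])
      sub <- d[(d$phase == "p" & d$year == yp) |
                 (d$phase == "s" & d$year == ysn), , drop = FALSE]
      pr <- fit_phase_interaction(sub)
      phase_rows[[id]] <- cbind(id = id, pr, stringsAsFactors = FALSE)
    }
    py <- unique(d$year[d$phase == "p"])
    if (length(py) >= 2) {
      yr <- fit_yearly(d[d$phase == "p", , drop = FALSE])
      year_rows[[id]] <- cbind(id = id, yr, stringsAsFactors = FALSE)
    }
  }
  phase_coefs <- if (length(phase_rows)) do.call(rbind, phase_rows) else NULL
  year_coefs <- if (length(year_rows)) do.call(rbind, year_rows) else NULL
  if (!is.null(phase_coefs))
    write.csv(phase_coefs, file.path(cfg$out_dir, "phase_coefficients.csv"),
              row.names = FALSE)
  if (!is.null(year_coefs))
    write.csv(year_coefs, file.path(cfg$out_dir, "year_coefficients.csv"),
              row.names = FALSE)

  # --- metrics with uncertainty -------------------------------------------
  rec <- data.frame(id = coefs$id, x = coefs$nhpi, se = coefs$se,
                    cluster = coefs$cluster, phase = coefs$phase,
                    stringsAsFactors = FALSE)
  rec <- rec[coefs$converged, , drop = FALSE]
  metr <- propagate_uncertainty(rec, by = "cluster", n_sim = cfg$n_sim,
                                seed = derive_seed(cfg$seed, "metrics"))
  write.csv(as.data.frame(metr), file.path(cfg$out_dir, "metrics.csv"),
            row.names = FALSE)
  pair_metr <- NULL
  if (!is.null(phase_coefs)) {
    prec <- data.frame(id = phase_coefs$id, phase = phase_coefs$phase,
                       x = phase_coefs$nhpi, se = phase_coefs$se,
                       stringsAsFactors = FALSE)
    pair_metr <- propagate_uncertainty(
      prec, metrics = c("consistency", "reversal"), n_sim = cfg$n_sim,
      seed = derive_seed(cfg$seed, "pair_metrics"))
    write.csv(as.data.frame(pair_metr),
              file.path(cfg$out_dir, "phase_metrics.csv"), row.names = FALSE)
  }

  # --- cross-validation ----------------------------------------------------
  cv <- do.call(rbind, lapply(names(designs), function(id) {
    d <- standardize_design(designs[[id]])
    r <- kfold_cv(d, k = cfg$cv_folds,
                  seed = derive_seed(cfg$seed, "cv", match(id, names(designs))))
    data.frame(id = id, rho_mean = r$mean, rho_sd = r$sd,
               stringsAsFactors = FALSE)
  }))
  write.csv(cv, file.path(cfg$out_dir, "cv.csv"), row.names = FALSE)

  manifest <- list(config = cfg[setdiff(names(cfg), "out_dir")],
                   package_version =
                     as.character(utils::packageVersion("nhpikit")),
                   counts = counts, step_rate = rate)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, landscape = landscape, nests = nests,
                 natal = natal, tracks = tracks, designs = designs,
                 coefficients = coefs, phase_coefficients = phase_coefs,
                 year_coefficients = year_coefs, metrics = metr,
                 phase_metrics = pair_metr, cv = cv))
}
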