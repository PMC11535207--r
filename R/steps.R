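#' Regularize a track to a fixed sampling interval
#'
#' Greedy regularization: starting from each burst anchor, keep the fix
#' closest to `anchor + interval` within `+/- tolerance` and advance; a gap
#' larger than `interval + tolerance` starts a new burst. Steps are later
#' built within bursts only, so no step spans a gap.
#'
#' @param track data.frame with at least `t` (numeric seconds or POSIXct,
#'   strictly increasing), `x`, `y`.
#' @param interval Target interval, seconds (default 3600).
#' @param tolerance Matching tolerance, seconds (default 900).
#' @return The kept fixes with a `burst` column. If fewer than 3 fixes
#'   survive, the track is flagged unusable (`attr(., "usable") = FALSE`)
#'   with a warning.
#' @export
resample_track <- function(track, interval = 3600, tolerance = 900) {
  stopifnot(all(c("t", "x", "y") %in% names(track)))
  tt <- as.numeric(track$t)
  if (is.unsorted(tt, strictly = TRUE)) stop("timestamps must be strictly increasing")
  n <- length(tt)
  keep <- integer(0); burst <- integer(0)
  i <- 1L; b <- 1L
  keep <- i; burst <- b
  while (TRUE) {
    target <- tt[i] + interval
    cand <- which(tt >= target - tolerance & tt <= target + tolerance)
    cand <- cand[cand > i]
    if (length(cand)) {
      i <- cand[which.min(abs(tt[cand] - target))]
      keep <- c(keep, i); burst <- c(burst, b)
    } else {
      nxt <- which(tt > target + tolerance)
      if (!length(nxt)) break
      i <- nxt[1L]; b <- b + 1L
      keep <- c(keep, i); burst <- c(burst, b)
    }
  }
  out <- track[keep, , drop = FALSE]
  out$burst <- burst
  rownames(out) <- NULL
  if (nrow(out) < 3) {
    warning("fewer than 3 fixes after resampling; track flagged unusable")
    attr(out, "usable") <- FALSE
  } else attr(out, "usable") <- TRUE
  out
}

#' Remove fixes implying unrealistic speeds
#'
#' Iteratively removes the arriving fix of any within-burst segment whose
#' implied speed exceeds `vmax`, until none remain.
#'
#' @param track data.frame with `t`, `x`, `y` and optionally `burst`.
#' @param vmax Maximum plausible speed, m/s (default 35).
#' @return The filtered track; `attr(., "n_removed")` records the count.
#' @export
speed_filter <- function(track, vmax = 35) {
  if (nrow(track) < 2) stop("need at least 2 fixes")
  burst <- if ("burst" %in% names(track)) track$burst else rep(1L, nrow(track))
  removed <- 0L
  repeat {
    tt <- as.numeric(track$t)
    n <- nrow(track)
    if (n < 2) break
    dt <- diff(tt); dd <- sqrt(diff(track$x)^2 + diff(track$y)^2)
    same <- burst[-1L] == burst[-n]
    v <- ifelse(same & dt > 0, dd / dt, 0)
    bad <- which(v > vmax)
    if (!length(bad)) break
    drop_i <- bad[1L] + 1L # arriving fix of the first offending segment
    track <- track[-drop_i, , drop = FALSE]
    burst <- burst[-drop_i]
    removed <- removed + 1L
  }
  track$burst <- burst
  rownames(track) <- NULL
  attr(track, "n_removed") <- removed
  track
}

wrap_angle <- function(a) {
  # wrap to (-pi, pi]
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

#' Build observed steps from a regularized track
#'
#' One step per consecutive within-burst fix pair. The turn angle is the
#' wrapped difference of successive absolute bearings; the first step of a
#' burst has no turn angle. Zero-length steps have no bearing of their own:
#' the bearing is carried forward from the last nonzero displacement, and a
#' step with no defined previous bearing cannot anchor a matched stratum.
#'
#' @param track Output of [resample_track()] (and usually [speed_filter()]).
#' @return data.frame of steps: start/end coordinates and times, `length`,
#'   `bearing`, `prev_bearing`, `turn`, plus any `phase`/`year` labels taken
#'   from the step's start fix.
#' @export
build_steps <- function(track) {
  burst <- if ("burst" %in% names(track)) track$burst else rep(1L, nrow(track))
  res <- list()
  for (b in unique(burst)) {
    tr <- track[burst == b, , drop = FALSE]
    if (nrow(tr) < 2) next
    n <- nrow(tr) - 1L
    dx <- diff(tr$x); dy <- diff(tr$y)
    len <- sqrt(dx^2 + dy^2)
    bearing <- ifelse(len > 0, atan2(dy, dx), NA_real_)
    # carry bearing forward over zero-length steps
    eff <- bearing
    for (i in seq_len(n)) if (is.na(eff[i]) && i > 1L) eff[i] <- eff[i - 1L]
    prev <- c(NA_real_, eff[-n])
    turn <- wrap_angle(bearing - prev)
    st <- data.frame(burst = b,
                     t1 = as.numeric(tr$t[-(n + 1L)]),
                     t2 = as.numeric(tr$t[-1L]),
                     x1 = tr$x[-(n + 1L)], y1 = tr$y[-(n + 1L)],
                     x2 = tr$x[-1L], y2 = tr$y[-1L],
                     length = len, bearing = bearing, prev_bearing = prev,
                     turn = turn)
    for (col in intersect(c("id", "phase", "year"), names(tr)))
      st[[col]] <- tr[[col]][-(n + 1L)]
    res[[length(res) + 1L]] <- st
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pooled exponential step-length distribution
#'
#' Maximum-likelihood exponential rate for the availability kernel,
#' parameterized by the observed step lengths pooled across the entire
#' population; zero-length steps are included in the mean.
#'
#' @param lengths Numeric vector of observed step lengths (meters).
#' @return The ML rate `1 / mean(lengths)` (per meter).
#' @export
fit_step_length_distribution <- function(lengths) {
  lengths <- lengths[is.finite(lengths)]
  if (!length(lengths) || all(lengths == 0))
    stop("step lengths are all zero or missing; cannot fit an exponential")
  1 / mean(lengths)
}

#' Sample available steps for one used step
#'
#' Draws `n_avail` alternative steps from the used step's start point:
#' lengths from the population exponential, turning angles uniform on
#' (-pi, pi) applied to the previous absolute bearing.
#'
#' @param step One row of [build_steps()] output with a defined
#'   `prev_bearing`.
#' @param n_avail Number of available steps (default 10).
#' @param rate Exponential rate from [fit_step_length_distribution()].
#' @param seed Optional seed (draws otherwise continue the caller's RNG
#'   stream).
#' @return data.frame of `n_avail + 1` rows (used first, `is_used` flag),
#'   with end coordinates.
#' @export
generate_available_steps <- function(step, n_avail = 10, rate, seed = NULL) {
  if (!is.finite(step$prev_bearing))
    stop("used step has no defined previous bearing")
  if (!is.null(seed)) set.seed(seed)
  len <- rexp(n_avail, rate)
  turn <- runif(n_avail, -pi, pi)
  ang <- step$prev_bearing + turn
  data.frame(is_used = c(TRUE, rep(FALSE, n_avail)),
             x = c(step$x2, step$x1 + len * cos(ang)),
             y = c(step$y2, step$y1 + len * sin(ang)),
             length = c(step$length, len),
             turn = c(step$turn, turn))
}

# fast path shared by the design builder and the track simulator: buffer
# composition -> PCA scores -> (dissimilarity, distance), all in matrices.
# Identical arithmetic to extract_buffer_composition() + project_habitat()
# + compute_dissimilarity() + compute_distance().
covariates_at <- function(landscape, pca, natal_scores, nest, px, py,
                          radius) {
  ncl <- length(landscape$classes)
  res <- cpp_buffer_composition(landscape$elevation, landscape$land_cover,
                                landscape$origin[1], landscape$origin[2],
                                landscape$cell_size, ncl,
                                as.numeric(px), as.numeric(py), radius)
  if (any(res[, ncl + 2L] == 0))
    stop("buffer contains no raster cell center for ",
         sum(res[, ncl + 2L] == 0), " point(s)")
  m <- res[, seq_len(ncl + 1L), drop = FALSE]
  colnames(m) <- habitat_vars()
  m <- m[, pca$variables, drop = FALSE]
  z <- sweep(sweep(m, 2, pca$means), 2, pca$sds, `/`)
  s <- z %*% pca$loadings[, seq_len(pca$k_retained), drop = FALSE]
  o <- as.numeric(natal_scores)[seq_len(pca$k_retained)]
  list(dissimilarity = sqrt(colSums((t(s) - o)^2)),
       distance = sqrt((px - nest[1])^2 + (py - nest[2])^2) / 1000)
}

#' Habitat dissimilarity to the natal territory
#'
#' The dissimilarity index: Euclidean distance, in the natal PCA space
#' (retained axes), between a location's habitat composition and the
#' individual's natal territory. Lower values mean habitats more similar to
#' the natal habitat.
#'
#' @param pca An `nhpi_pca` model.
#' @param natal Natal PC scores (length `k_retained`), or a natal habitat
#'   vector to be projected.
#' @param v Habitat vector (or data.frame of them) at the location(s) of
#'   interest, e.g. a step end-location buffer composition.
#' @return Numeric dissimilarity value(s).
#' @export
compute_dissimilarity <- function(pca, natal, v) {
  k <- pca$k_retained
  o <- if (!is.null(names(natal)) && all(pca$variables %in% names(natal)))
    project_habitat(pca, natal) else as.numeric(natal)[seq_len(k)]
  s <- project_habitat(pca, v)
  if (is.null(dim(s))) sqrt(sum((s - o)^2)) else
    sqrt(colSums((t(s) - o)^2))
}

#' Distance to the natal nest
#'
#' Planar Euclidean distance from location(s) to the natal nest, in
#' kilometers.
#'
#' @param nest Numeric `(x, y)` of the nest, meters.
#' @param p Numeric `(x, y)` or a 2-column matrix of locations, meters.
#' @return Distance(s) in km.
#' @export
compute_distance <- function(nest, p) {
  if (is.null(dim(p))) sqrt(sum((as.numeric(p) - as.numeric(nest))^2)) / 1000
  else sqrt((p[, 1] - nest[1])^2 + (p[, 2] - nest[2])^2) / 1000
}

#' Build the matched used/available design for one individual
#'
#' For every observed step with a defined previous bearing, samples
#' `n_avail` available steps (exponential lengths, uniform turns), computes
#' the two covariates at every end-location (habitat dissimilarity to the
#' natal territory and distance to the natal nest), and assembles the
#' matched strata.
#'
#' Availability proposals falling outside the landscape are redrawn up to
#' `max_redraw` times (the synthetic-mode convention; the observed process
#' is bounded the same way). If `drop_oob = TRUE` instead, out-of-bounds
#' available rows are dropped with a message (real-data convention).
#'
#' @param steps Output of [build_steps()].
#' @param landscape A [landscape_raster()].
#' @param pca An `nhpi_pca` model.
#' @param natal_scores Natal PC scores for this individual.
#' @param nest Nest `(x, y)`, meters.
#' @param n_avail Available steps per stratum (default 10).
#' @param rate Exponential rate for available step lengths.
#' @param seed Integer seed for the availability draws.
#' @param radius Buffer radius for end-location composition, meters.
#' @param drop_oob Drop rather than redraw out-of-bounds proposals.
#' @param max_redraw Redraw attempts per proposal.
#' @return data.frame: `stratum`, `is_used`, `x`, `y`, `dissimilarity`,
#'   `distance` (km), plus `phase`/`year` carried from the used step.
#' @export
build_design <- function(steps, landscape, pca, natal_scores, nest,
                         n_avail = 10, rate, seed, radius = 2000,
                         drop_oob = FALSE, max_redraw = 20) {
  el <- steps[is.finite(steps$prev_bearing), , drop = FALSE]
  if (!nrow(el)) stop("no steps with a defined previous bearing")
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  ns <- nrow(el)

  len <- matrix(rexp(ns * n_avail, rate), ns, n_avail)
  turn <- matrix(runif(ns * n_avail, -pi, pi), ns, n_avail)
  ax <- el$x1 + len * cos(el$prev_bearing + turn)
  ay <- el$y1 + len * sin(el$prev_bearing + turn)
  if (!drop_oob) {
    for (try in seq_len(max_redraw)) {
      oob <- !in_landscape(landscape, ax, ay)
      if (!any(oob)) break
      idx <- which(oob)
      row_i <- (idx - 1L) %% ns + 1L
      l2 <- rexp(length(idx), rate); t2 <- runif(length(idx), -pi, pi)
      ax[idx] <- el$x1[row_i] + l2 * cos(el$prev_bearing[row_i] + t2)
      ay[idx] <- el$y1[row_i] + l2 * sin(el$prev_bearing[row_i] + t2)
    }
    if (any(!in_landscape(landscape, ax, ay)))
      stop("available-step proposals still out of bounds after ",
           max_redraw, " redraws")
  }

  stratum <- rep(seq_len(ns), each = n_avail + 1L)
  is_used <- rep(c(TRUE, rep(FALSE, n_avail)), ns)
  xs <- as.vector(rbind(el$x2, t(ax)))
  ys <- as.vector(rbind(el$y2, t(ay)))
  des <- data.frame(stratum = stratum, is_used = is_used, x = xs, y = ys)
  for (col in intersect(c("id", "phase", "year"), names(el)))
    des[[col]] <- rep(el[[col]], each = n_avail + 1L)

  keep <- in_landscape(landscape, des$x, des$y)
  if (drop_oob && any(!keep)) {
    message("dropping ", sum(!keep), " out-of-bounds available row(s)")
    des <- des[keep, , drop = FALSE]
  }
  cv <- covariates_at(landscape, pca, natal_scores, nest, des$x, des$y,
                      radius)
  des$dissimilarity <- cv$dissimilarity
  des$distance <- cv$distance
  rownames(des) <- NULL
  des
}

#' Standardize design covariates
#'
#' Centers and scales covariates over all rows (used and available) of the
#' model's dataset, recording the scaling so that coefficients can be
#' back-transformed to the raw scale (`beta_raw = beta_z / sd`). Also
#' reports the Pearson correlation between the covariates as a collinearity
#' check.
#'
#' @param design A design table from [build_design()].
#' @param covariates Covariate columns to standardize.
#' @return The design with added `<cov>_z` columns;
#'   `attr(., "scaling")` holds means/SDs, `attr(., "correlation")` the
#'   covariate correlation matrix.
#' @export
standardize_design <- function(design,
                               covariates = c("dissimilarity", "distance")) {
  sc <- data.frame(covariate = covariates, mean = NA_real_, sd = NA_real_)
  for (i in seq_along(covariates)) {
    v <- design[[covariates[i]]]
    mu <- mean(v); s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop("covariate '", covariates[i], "' has zero SD; cannot standardize")
    design[[paste0(covariates[i], "_z")]] <- (v - mu) / s
    sc$mean[i] <- mu; sc$sd[i] <- s
  }
  attr(design, "scaling") <- sc
  if (length(covariates) > 1)
    attr(design, "correlation") <-
      cor(design[, covariates, drop = FALSE])
  design
}
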