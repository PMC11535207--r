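#' Simulate an hourly trajectory under a known step-selection process
#'
#' Generates a track by, at every step, proposing `n_candidates` candidate
#' steps (length from `Exponential(step_rate)`, turning angle uniform on
#' (-pi, pi) relative to the previous bearing) and choosing one with
#' probability proportional to
#' `exp(beta_dissim * dissimilarity + beta_dist * distance)`. The covariates
#' are computed exactly as the analysis computes them: habitat dissimilarity
#' is the natal-PCA-space distance of the end-location's 2 km buffer
#' composition to the natal territory, distance is the planar distance to
#' the natal nest in km. Out-of-bounds proposals are rejected and redrawn,
#' so the realized availability kernel is the same truncated kernel the
#' analysis samples from.
#'
#' Selection coefficients are on the RAW covariate scale. When the fitted
#' (standardized-scale) coefficients are compared with the truth, convert
#' with the realized covariate SD of the model dataset:
#' `beta_std = beta_raw * sd(covariate)`.
#'
#' @param landscape A [landscape_raster()].
#' @param pca An `nhpi_pca` fitted on the cohort's natal habitat vectors.
#' @param individual List with `id`, `nest` (x, y), `beta_dissim`,
#'   `beta_dist` (raw scale), and either `n_steps` or a `segments`
#'   data.frame (`phase`, `year`, `n_steps`) for multi-phase tracks.
#' @param step_rate Exponential rate of proposal step lengths (1/meters).
#' @param n_candidates Candidate steps per move (default 300). The discrete
#'   softmax over a finite candidate set approximates the continuous
#'   availability distribution with a bias of order `1/n_candidates` in the
#'   recovered coefficients; a few hundred candidates push that bias below
#'   the Monte-Carlo noise of a 1,000-step track, where a few dozen leave a
#'   visible attenuation at coefficient magnitudes near 1.
#' @param seed Integer seed; fixed seed reproduces the track exactly.
#' @param radius Buffer radius for the dissimilarity covariate, meters.
#' @param t0 Start time, seconds (fixes are hourly from `t0`).
#' @param max_rounds Redraw rounds before giving up on a boxed-in position.
#' @return Track data.frame: `id`, `t`, `x`, `y`, `phase`, `year`, `burst`.
#'   The first row is the start position (the nest).
#' @export
simulate_track <- function(landscape, pca, individual, step_rate,
                           n_candidates = 300, seed, radius = 2000,
                           t0 = 0, max_rounds = 200) {
  if (missing(seed)) stop("seed is required")
  if (n_candidates < 2) stop("n_candidates must be >= 2")
  nest <- as.numeric(individual$nest)
  if (!in_landscape(landscape, nest[1], nest[2]))
    stop("nest lies outside the landscape")
  segs <- if (!is.null(individual$segments)) individual$segments else
    data.frame(phase = "p", year = 1L,
               n_steps = individual$n_steps, stringsAsFactors = FALSE)
  n_steps <- sum(segs$n_steps)
  if (n_steps < 3) stop("n_steps must be >= 3")
  bd <- individual$beta_dissim; bt <- individual$beta_dist
  if (!is.finite(bd) || !is.finite(bt)) stop("coefficients must be finite")
  set.seed(seed)

  natal_comp <- extract_buffer_composition(landscape, nest, radius)
  natal_sc <- project_habitat(pca, natal_comp)

  xs <- ys <- numeric(n_steps + 1L)
  xs[1L] <- nest[1]; ys[1L] <- nest[2]
  bearing <- runif(1, -pi, pi) # initial heading
  for (s in seq_len(n_steps)) {
    # draw candidates, redrawing out-of-bounds proposals
    cx <- cy <- cb <- rep(NA_real_, n_candidates)
    need <- seq_len(n_candidates)
    for (round in seq_len(max_rounds)) {
      len <- rexp(length(need), step_rate)
      trn <- runif(length(need), -pi, pi)
      ang <- bearing + trn
      px <- xs[s] + len * cos(ang); py <- ys[s] + len * sin(ang)
      okp <- in_landscape(landscape, px, py)
      cx[need[okp]] <- px[okp]; cy[need[okp]] <- py[okp]
      cb[need[okp]] <- ang[okp]
      need <- need[!okp]
      if (!length(need)) break
    }
    if (length(need))
      stop("could not propose in-bounds candidates after ", max_rounds,
           " rounds at step ", s)
    cv <- covariates_at(landscape, pca, natal_sc, nest, cx, cy, radius)
    w <- exp(bd * cv$dissimilarity + bt * cv$distance)
    pick <- sample.int(n_candidates, 1L, prob = w / sum(w))
    xs[s + 1L] <- cx[pick]; ys[s + 1L] <- cy[pick]
    bearing <- cb[pick]
  }
  data.frame(id = individual$id, t = t0 + 3600 * (0:n_steps),
             x = xs, y = ys,
             phase = c(segs$phase[1L], rep(segs$phase, segs$n_steps)),
             year = c(segs$year[1L], rep(segs$year, segs$n_steps)),
             burst = 1L, stringsAsFactors = FALSE)
}

#' Simulate bare coefficient tables
#'
#' Direct fixture for the metric layer: one record per individual x phase
#' with coefficient drawn from `Normal(mean, sd)` and a fixed standard
#' error.
#'
#' @param n_ids Number of individuals.
#' @param mean,sd Normal parameters of the coefficient distribution
#'   (`sd >= 0`).
#' @param se_scale Standard error attached to every record (`>= 0`).
#' @param phases Character vector of phase labels (one record per
#'   individual per phase).
#' @param seed Integer seed.
#' @return data.frame: `id`, `phase`, `x`, `se`.
#' @export
simulate_coefficients <- function(n_ids, mean = 0, sd = 1, se_scale = 0.1,
                                  phases = "p", seed) {
  if (missing(seed)) stop("seed is required")
  if (sd < 0 || se_scale < 0) stop("sd and se_scale must be >= 0")
  set.seed(seed)
  ids <- sprintf("ind%03d", seq_len(n_ids))
  out <- expand.grid(id = ids, phase = phases, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$id, out$phase), , drop = FALSE]
  out$x <- rnorm(nrow(out), mean, sd)
  out$se <- se_scale
  rownames(out) <- NULL
  out
}

#' Estimate raw covariate scales near a nest
#'
#' Monte-Carlo estimate of the SD of the two covariates over the truncated
#' availability kernel around a nest: proposals are drawn exactly as
#' [simulate_track()] proposes steps from the nest. Used to choose raw-scale
#' simulation coefficients that land near a target standardized-scale
#' value (`beta_raw = beta_std / sd`).
#'
#' @param landscape,pca,nest As in [simulate_track()].
#' @param step_rate Proposal exponential rate (1/m).
#' @param n Number of proposals.
#' @param seed Integer seed.
#' @param radius Buffer radius, meters.
#' @return List with `sd_dissimilarity` and `sd_distance`.
#' @export
estimate_covariate_scale <- function(landscape, pca, nest, step_rate,
                                     n = 2000, seed, radius = 2000) {
  set.seed(seed)
  nest <- as.numeric(nest)
  natal_sc <- project_habitat(
    pca, extract_buffer_composition(landscape, nest, radius))
  pts <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  # two-step proposals from the nest: a first hop sets the position spread
  for (round in 1:200) {
    len <- rexp(length(need), step_rate) + rexp(length(need), step_rate)
    ang <- runif(length(need), -pi, pi)
    px <- nest[1] + len * cos(ang); py <- nest[2] + len * sin(ang)
    okp <- in_landscape(landscape, px, py)
    pts[need[okp], ] <- cbind(px[okp], py[okp])
    need <- need[!okp]
    if (!length(need)) break
  }
  pts <- pts[complete.cases(pts), , drop = FALSE]
  cv <- covariates_at(landscape, pca, natal_sc, nest, pts[, 1], pts[, 2],
                      radius)
  list(sd_dissimilarity = sd(cv$dissimilarity),
       sd_distance = sd(cv$distance))
}
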