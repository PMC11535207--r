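# Independent oracles and shared fixtures.

# uniform landscape of one cover class on a flat (or sloped) elevation grid
uniform_landscape <- function(class = "forest", n = 60, cell = 100,
                              elev = 700) {
  code <- match(class, nhpi_classes())
  landscape_raster(matrix(elev, n, n), matrix(code, n, n),
                   cell_size = cell)
}

# left half arable, right half forest (split between columns n/2 and n/2+1)
half_plane_landscape <- function(n = 60, cell = 100) {
  lc <- matrix(match("forest", nhpi_classes()), n, n)
  lc[, seq_len(n %/% 2)] <- match("arable", nhpi_classes())
  landscape_raster(matrix(600, n, n), lc, cell_size = cell)
}

# hand-built 2-variable PCA model (loadings [1/sqrt2, 1/sqrt2] on PC1)
toy_pca <- function() {
  vars <- c("elevation", "prop_forest")
  structure(list(
    means = setNames(c(700, 0.5), vars),
    sds = setNames(c(100, 0.2), vars),
    loadings = matrix(c(1, 1, 1, -1) / sqrt(2), 2,
                      dimnames = list(vars, c("PC1", "PC2"))),
    explained_fraction = c(0.6, 0.4), k_retained = 2,
    variables = vars, scores = NULL), class = "nhpi_pca")
}

# brute-force cell enumeration for buffer composition
brute_buffer <- function(landscape, point, radius) {
  ctr <- expand.grid(
    i = seq_len(landscape$n_rows), j = seq_len(landscape$n_cols))
  ctr$x <- landscape$origin[1] + (ctr$j - 0.5) * landscape$cell_size
  ctr$y <- landscape$origin[2] + (ctr$i - 0.5) * landscape$cell_size
  keep <- (ctr$x - point[1])^2 + (ctr$y - point[2])^2 <= radius^2
  ctr <- ctr[keep, , drop = FALSE]
  el <- landscape$elevation[cbind(ctr$i, ctr$j)]
  lc <- landscape$land_cover[cbind(ctr$i, ctr$j)]
  props <- vapply(seq_along(nhpi_classes()), function(k) mean(lc == k), 0)
  c(elevation = mean(el), setNames(props, paste0("prop_", nhpi_classes())),
    n = nrow(ctr))
}

# brute-force grid maximization of the conditional log-likelihood
# (1 or 2 covariates)
grid_clogit <- function(design, covariates, lo = -5, hi = 5, step = 1e-4) {
  X <- as.matrix(design[, covariates, drop = FALSE])
  y <- design$is_used
  si <- design$stratum
  ll <- function(beta) {
    eta <- drop(X %*% beta)
    sum(eta[y]) - sum(log(tapply(exp(eta), si, sum)))
  }
  if (length(covariates) == 1L) {
    # coarse-to-fine scan keeps the 1e-4 resolution tractable
    grid <- seq(lo, hi, by = 0.01)
    b <- grid[which.max(vapply(grid, ll, 0))]
    grid <- seq(b - 0.02, b + 0.02, by = step)
    grid[which.max(vapply(grid, ll, 0))]
  } else {
    grid <- seq(lo, hi, by = 0.05)
    vals <- outer(grid, grid, Vectorize(function(a, b) ll(c(a, b))))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    b <- c(grid[ix[1]], grid[ix[2]])
    g1 <- seq(b[1] - 0.1, b[1] + 0.1, by = step)
    g2 <- seq(b[2] - 0.1, b[2] + 0.1, by = step)
    vals <- outer(g1, g2, Vectorize(function(a, bb) ll(c(a, bb))))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    c(g1[ix[1]], g2[ix[2]])
  }
}

# O(n^3) brute-force complete-linkage agglomeration -> labels at k clusters
brute_complete_linkage <- function(points, k) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      h <- max(d[clusters[[a]], clusters[[b]]])
      if (h < best[1]) best <- c(h, a, b)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# small hand-built design: 3 strata, 1 covariate (values chosen free of ties)
hand_strata <- function() {
  data.frame(
    stratum = rep(1:3, each = 3),
    is_used = rep(c(TRUE, FALSE, FALSE), 3),
    z = c(0.5, -0.3, 0.8,
          1.2, 0.1, -0.7,
          -0.2, 0.9, 0.4))
}

# shared medium fixture: landscape + nests + natal model + one simulated
# individual with its design (memoized across test files)
.fixture_env <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  ls1 <- generate_landscape(seed = 101)
  nests <- place_nests(ls1, 10, seed = 102)
  natal <- assign_natal_habitats(ls1, nests)
  ind <- list(id = "fx1", nest = c(nests$x[3], nests$y[3]),
              beta_dissim = -1.5, beta_dist = -0.05, n_steps = 250)
  track <- simulate_track(ls1, natal$pca, ind, step_rate = 1 / 600,
                          seed = 103)
  steps <- build_steps(track)
  rate <- fit_step_length_distribution(steps$length)
  design <- build_design(steps, ls1, natal$pca, natal$pca$scores[3, ],
                         nest = ind$nest, rate = rate, seed = 104)
  .fixture_env$fx <- list(landscape = ls1, nests = nests, natal = natal,
                          ind = ind, track = track, steps = steps,
                          rate = rate, design = design)
  .fixture_env$fx
}
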