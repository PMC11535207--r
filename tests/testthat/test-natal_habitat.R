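test_that("buffer composition handles uniform and split landscapes", {
  lf <- uniform_landscape("forest", elev = 712)
  v <- extract_buffer_composition(lf, c(3000, 3000), radius = 2000)
  expect_equal(unname(v["prop_forest"]), 1)
  expect_equal(sum(v[paste0("prop_", nhpi_classes())]), 1)
  expect_equal(unname(v["elevation"]), 712)

  hp <- half_plane_landscape()
  # point on the class boundary: halves balance to within 2 cells' worth
  mid <- 30 * 100
  v <- extract_buffer_composition(hp, c(mid, 3000), radius = 2000)
  n_cells <- brute_buffer(hp, c(mid, 3000), 2000)["n"]
  expect_lt(abs(v[["prop_arable"]] - 0.5), 2 * 100 / (2 * 2000)) # loose
  expect_equal(v[["prop_arable"]] + v[["prop_forest"]], 1)
  expect_gt(n_cells, 1200) # pi * 20^2 ~ 1257 cell centers

  expect_error(extract_buffer_composition(lf, c(1e6, 1e6), radius = 2000),
               "no raster cell center")
})

test_that("buffer composition matches brute-force cell enumeration", {
  fx <- shared_fixture()
  set.seed(40)
  pts <- cbind(runif(5, 2500, 9500), runif(5, 2500, 9500))
  got <- extract_buffer_composition(fx$landscape, pts, radius = 2000)
  for (i in 1:5) {
    want <- brute_buffer(fx$landscape, pts[i, ], 2000)
    expect_equal(unlist(got[i, ]), want[habitat_vars()], tolerance = 1e-12)
  }
})

test_that("the natal PCA equals the eigendecomposition of the correlation matrix", {
  set.seed(41)
  m <- as.data.frame(matrix(rnorm(20 * 7), 20, 7))
  names(m) <- habitat_vars()
  pca <- fit_natal_pca(m, k_retained = 2)

  # orthonormal loadings, variance fractions sum to 1
  g <- crossprod(pca$loadings)
  expect_equal(g, diag(7), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$explained_fraction) <= 1e-12))

  # oracle: eigen of the correlation matrix
  ev <- eigen(cor(as.matrix(m)), symmetric = TRUE)
  expect_equal(pca$explained_fraction, ev$values / sum(ev$values),
               tolerance = 1e-9)
  for (j in 1:7) # loadings match up to sign
    expect_equal(min(sum(abs(pca$loadings[, j] - ev$vectors[, j])),
                     sum(abs(pca$loadings[, j] + ev$vectors[, j]))),
                 0, tolerance = 1e-8)
  # sign convention: dominant loading of each axis positive
  for (j in 1:7)
    expect_gte(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("degenerate PCA inputs are dropped or rejected", {
  base <- as.data.frame(matrix(0.5, 10, 7))
  names(base) <- habitat_vars()
  expect_error(fit_natal_pca(base), "zero variance")

  # two perfectly correlated variables, the rest constant -> rank 1
  two <- base
  two$elevation <- 1:10
  two$prop_forest <- 2 * (1:10) + 3
  expect_warning(pca <- fit_natal_pca(two), "zero-variance")
  expect_equal(length(pca$variables), 2L)
  expect_equal(pca$explained_fraction[1], 1, tolerance = 1e-12)
})

test_that("projection is centered, idempotent on training data, and exact", {
  fx <- shared_fixture()
  pca <- fx$natal$pca
  at_mean <- setNames(as.numeric(pca$means), pca$variables)
  expect_equal(unname(project_habitat(pca, at_mean)), c(0, 0),
               tolerance = 1e-12)

  comp <- extract_buffer_composition(
    fx$landscape, as.matrix(fx$nests[, c("x", "y")]), radius = 2000)
  re <- project_habitat(pca, comp)
  expect_equal(unname(re), unname(pca$scores), tolerance = 1e-9)

  # hand-built 2-variable model: +1 SD on both variables -> PC1 = sqrt(2)
  toy <- toy_pca()
  v <- setNames(toy$means + toy$sds, toy$variables)
  expect_equal(unname(project_habitat(toy, v)), c(sqrt(2), 0),
               tolerance = 1e-12)

  expect_error(project_habitat(pca, data.frame(elevation = 1)), "missing")
})

test_that("complete-linkage clustering recovers separated clouds and k", {
  set.seed(42)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  pts <- centers[rep(1:4, each = 6), ] + matrix(rnorm(48, 0, 0.01), 24, 2)
  truth <- rep(1:4, each = 6)
  cl <- cluster_natal_habitats(pts, k = 4)
  expect_true(same_partition(cl$labels, truth))
  auto <- cluster_natal_habitats(pts, k = "auto")
  expect_equal(auto$k, 4L)
  expect_true(all(diff(cl$merge_heights) >= -1e-12)) # monotone merges

  # k = n: each point its own cluster
  kn <- cluster_natal_habitats(pts[1:5, ], k = 5)
  expect_equal(sort(kn$labels), 1:5)

  expect_error(cluster_natal_habitats(pts[1, , drop = FALSE]), "at least 2")
})

test_that("clustering agrees with a brute-force agglomerative oracle", {
  # 6 hand-sized points, k = 2, then random configurations up to n = 12
  six <- cbind(c(0, 0.4, 1.1, 6.0, 6.3, 7.2), c(0, 0.5, 0.2, 3.0, 3.3, 2.8))
  cl <- cluster_natal_habitats(six, k = 2)
  expect_true(same_partition(cl$labels, brute_complete_linkage(six, 2)))

  set.seed(43)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    pts <- matrix(runif(2 * n, 0, 10), n, 2)
    cl <- cluster_natal_habitats(pts, k = k)
    expect_true(same_partition(cl$labels, brute_complete_linkage(pts, k)))
  }
})

test_that("downstream quantities are invariant to PC sign flips", {
  fx <- shared_fixture()
  pca <- fx$natal$pca
  flipped <- pca
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  flipped$scores <- NULL

  comp <- extract_buffer_composition(
    fx$landscape, as.matrix(fx$nests[, c("x", "y")]), radius = 2000)
  natal_v <- unlist(comp[3, ])
  d1 <- compute_dissimilarity(pca, natal_v, comp)
  d2 <- compute_dissimilarity(flipped, natal_v, comp)
  expect_equal(d1, d2, tolerance = 1e-12)

  s1 <- project_habitat(pca, comp)
  s2 <- project_habitat(flipped, comp)
  c1 <- cluster_natal_habitats(s1, k = 3)
  c2 <- cluster_natal_habitats(s2, k = 3)
  expect_true(same_partition(c1$labels, c2$labels))
})

test_that("the PCA model round-trips through JSON", {
  fx <- shared_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_pca_json(fx$natal$pca, path)
  back <- read_pca_json(path)
  expect_equal(unname(back$means), unname(fx$natal$pca$means))
  expect_equal(unname(back$loadings), unname(fx$natal$pca$loadings),
               tolerance = 1e-12)
  v <- setNames(as.numeric(fx$natal$pca$means) +
                  as.numeric(fx$natal$pca$sds), back$variables)
  expect_equal(project_habitat(back, v), project_habitat(fx$natal$pca, v),
               tolerance = 1e-12)
})
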