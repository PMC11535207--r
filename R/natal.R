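#' Habitat composition within a buffer
#'
#' Summarizes the landscape within a disc of `radius` around one or more
#' points: mean elevation and the proportion of each land-cover class over
#' all cells whose center falls inside the disc. Buffers clipped by the
#' raster edge are renormalized over the in-raster cells.
#'
#' @param landscape A [landscape_raster()] object.
#' @param point Numeric `(x, y)` in meters, or a 2-column matrix/data.frame
#'   of points.
#' @param radius Buffer radius in meters (default 2000, the standard
#'   territory radius used throughout).
#' @return For one point, a named numeric habitat vector (`elevation`,
#'   `prop_arable`, ..., `prop_mosaic`); for several, a data.frame with one
#'   row per point.
#' @export
extract_buffer_composition <- function(landscape, point, radius = 2000) {
  pts <- if (is.null(dim(point))) matrix(as.numeric(point), 1L) else
    as.matrix(point)[, 1:2, drop = FALSE]
  res <- cpp_buffer_composition(landscape$elevation, landscape$land_cover,
                                landscape$origin[1], landscape$origin[2],
                                landscape$cell_size,
                                length(landscape$classes),
                                as.numeric(pts[, 1]), as.numeric(pts[, 2]),
                                radius)
  ncl <- length(landscape$classes)
  if (any(res[, ncl + 2L] == 0))
    stop("buffer contains no raster cell center for ",
         sum(res[, ncl + 2L] == 0), " point(s)")
  out <- as.data.frame(res[, seq_len(ncl + 1L), drop = FALSE])
  names(out) <- habitat_vars()
  if (nrow(pts) == 1L) unlist(out[1L, ]) else out
}

#' Fit the natal-habitat principal component analysis
#'
#' Centers and scales each habitat descriptor (SD with the n-1 denominator)
#' and extracts the principal axes of the correlation matrix. This is the
#' shared low-dimensional habitat space: natal territories and step
#' end-locations are both projected into it, and the habitat dissimilarity
#' index is the Euclidean distance between their scores on the first
#' `k_retained` axes.
#'
#' Zero-variance descriptors are dropped with a warning (they carry no
#' information for a correlation PCA). Axis signs are oriented so that each
#' axis' largest-magnitude loading is positive; every downstream quantity is
#' invariant to these signs.
#'
#' @param vectors data.frame of habitat vectors, columns as produced by
#'   [extract_buffer_composition()] (at least 3 rows).
#' @param k_retained Number of axes retained for projection and
#'   dissimilarity (default 2).
#' @return An object of class `nhpi_pca`: list with `means`, `sds`,
#'   `loadings` (variables x axes, orthonormal columns),
#'   `explained_fraction`, `k_retained`, `variables`, and the training
#'   `scores` on the retained axes.
#' @export
fit_natal_pca <- function(vectors, k_retained = 2) {
  m <- as.matrix(vectors[, intersect(habitat_vars(), names(vectors)),
                         drop = FALSE])
  if (nrow(m) < 3) stop("need at least 3 habitat vectors")
  sds <- apply(m, 2, sd)
  if (all(sds == 0)) stop("all habitat descriptors have zero variance")
  if (any(sds == 0)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each axis positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  ev <- pc$sdev^2
  k <- min(k_retained, ncol(rot))
  scores <- scale(m, center = pc$center, scale = pc$scale) %*%
    rot[, seq_len(k), drop = FALSE]
  structure(list(means = pc$center, sds = pc$scale, loadings = rot,
                 explained_fraction = ev / sum(ev), k_retained = k,
                 variables = colnames(m), scores = scores),
            class = "nhpi_pca")
}

#' @export
print.nhpi_pca <- function(x, ...) {
  cat("<nhpi_pca> ", length(x$variables), " variables, ",
      x$k_retained, " retained axes\n", sep = "")
  cat("  explained: ",
      paste0(round(100 * x$explained_fraction[seq_len(x$k_retained)], 1),
             "%", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Project habitat vectors into the natal PCA space
#'
#' @param pca An `nhpi_pca` model.
#' @param v A named habitat vector, or a data.frame of them; must contain
#'   every variable the model was fitted on.
#' @return Numeric score vector (one point) or matrix (several points) on
#'   the retained axes.
#' @export
project_habitat <- function(pca, v) {
  one <- is.null(dim(v))
  m <- if (one) matrix(as.numeric(v[pca$variables]), 1L,
                       dimnames = list(NULL, pca$variables)) else {
    if (!all(pca$variables %in% names(v)))
      stop("missing variable(s): ",
           paste(setdiff(pca$variables, names(v)), collapse = ", "))
    as.matrix(v[, pca$variables, drop = FALSE])
  }
  if (any(is.na(m))) stop("habitat vector contains missing values")
  z <- sweep(sweep(m, 2, pca$means), 2, pca$sds, `/`)
  s <- z %*% pca$loadings[, seq_len(pca$k_retained), drop = FALSE]
  if (one) drop(s) else s
}

#' Cluster natal habitats by furthest-neighbour agglomeration
#'
#' Complete-linkage (furthest neighbour) hierarchical clustering on
#' Euclidean distances between natal PCA scores, cut at `k` clusters.
#' Labels are relabeled in order of descending cluster size.
#'
#' @param scores Numeric matrix of natal PC scores (individuals x axes).
#' @param k Number of clusters, or `"auto"`: scan `k` in
#'   `2..min(10, n - 1)` and keep the cut with the largest relative drop in
#'   within-cluster inertia between consecutive cuts.
#' @return List with `labels` (integer vector, 1 = largest cluster),
#'   `k`, `merge_heights` (the dendrogram heights, non-decreasing), and the
#'   `hclust` object.
#' @export
cluster_natal_habitats <- function(scores, k = "auto") {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2) stop("need at least 2 points to cluster")
  hc <- hclust(dist(scores), method = "complete")
  if (identical(k, "auto")) {
    # cut where the dendrogram's merge heights jump the most in relative
    # terms: cutting at k clusters separates merge n-k (height below the
    # cut) from merge n-k+1 (the merge the cut undoes)
    kmax <- min(10L, n - 1L)
    hs <- hc$height
    ratio <- vapply(2:kmax, function(kk)
      hs[n - kk + 1L] / max(hs[n - kk], .Machine$double.eps), 0)
    k <- which.max(ratio) + 1L
  }
  if (k < 2 || k > n) stop("k must be in 2..n")
  lab <- cutree(hc, k = k)
  # relabel by descending cluster size (ties: first-seen order)
  sizes <- sort(table(lab), decreasing = TRUE)
  lab <- match(lab, as.integer(names(sizes)))
  list(labels = lab, k = as.integer(k), merge_heights = hc$height,
       hclust = hc)
}

#' Assign natal habitats for a cohort of nests
#'
#' Full natal characterization: buffer composition around every nest, the
#' scaled PCA over the cohort, projection of each natal territory into the
#' retained PC space, and the habitat-type clustering.
#'
#' @param landscape A [landscape_raster()] object.
#' @param nests data.frame with `id`, `x`, `y`.
#' @param radius Territory buffer radius, meters.
#' @param k Cluster count or `"auto"` (see [cluster_natal_habitats()]).
#' @param k_retained Retained PCA axes.
#' @return List with `assignment` (data.frame: id, habitat descriptors,
#'   PC scores, `cluster`), `pca` (`nhpi_pca`), and `clustering`.
#' @export
assign_natal_habitats <- function(landscape, nests, radius = 2000,
                                  k = "auto", k_retained = 2) {
  comp <- extract_buffer_composition(landscape, nests[, c("x", "y")], radius)
  pca <- fit_natal_pca(comp, k_retained = k_retained)
  scores <- pca$scores
  cl <- cluster_natal_habitats(scores, k = k)
  out <- cbind(data.frame(id = nests$id, stringsAsFactors = FALSE), comp,
               setNames(as.data.frame(scores),
                        paste0("PC", seq_len(ncol(scores)))),
               cluster = cl$labels)
  list(assignment = out, pca = pca, clustering = cl)
}

#' Save / load an `nhpi_pca` model as JSON
#'
#' @param pca An `nhpi_pca` model.
#' @param path JSON file path.
#' @export
write_pca_json <- function(pca, path) {
  jsonlite::write_json(
    list(variables = pca$variables, means = unname(pca$means),
         sds = unname(pca$sds),
         loadings = unname(apply(pca$loadings, 2, identity, simplify = FALSE)),
         explained_fraction = unname(pca$explained_fraction),
         k_retained = pca$k_retained),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  # loadings are serialized column by column; simplification stacks each
  # column as a row, so transpose back
  loadings <- if (is.list(j$loadings)) do.call(cbind, j$loadings) else
    t(as.matrix(j$loadings))
  dimnames(loadings) <- list(j$variables,
                             paste0("PC", seq_len(ncol(loadings))))
  structure(list(means = setNames(j$means, j$variables),
                 sds = setNames(j$sds, j$variables), loadings = loadings,
                 explained_fraction = j$explained_fraction,
                 k_retained = j$k_retained, variables = j$variables,
                 scores = NULL),
            class = "nhpi_pca")
}
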