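#' Landscape raster container
#'
#' Bundles co-registered elevation and land-cover grids on a planar metric
#' coordinate system. Grids are stored bottom-up: row `i`, column `j` has its
#' cell center at `(x0 + (j - 0.5) * cell_size, y0 + (i - 0.5) * cell_size)`
#' where `(x0, y0)` is the lower-left corner of the grid.
#'
#' @param elevation Numeric matrix of cell elevations (meters).
#' @param land_cover Integer matrix of land-cover codes (1-6, see
#'   [nhpi_classes()]); same dimensions as `elevation`.
#' @param origin Numeric length-2, lower-left corner `(x0, y0)` in meters.
#' @param cell_size Cell edge length in meters (default 100).
#' @return An object of class `LandscapeRaster`.
#' @export
landscape_raster <- function(elevation, land_cover, origin = c(0, 0),
                             cell_size = 100) {
  if (!is.matrix(elevation) || !is.matrix(land_cover))
    stop("elevation and land_cover must be matrices")
  if (!all(dim(elevation) == dim(land_cover)))
    stop("elevation and land_cover grids differ in shape")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive scalar")
  if (any(!is.finite(elevation)))
    stop("elevation must be finite everywhere")
  cls <- nhpi_classes()
  lc <- matrix(as.integer(land_cover), nrow(land_cover), ncol(land_cover))
  if (any(is.na(lc)) || any(lc < 1L) || any(lc > length(cls)))
    stop("land_cover codes must be integers in 1..", length(cls))
  structure(list(origin = as.numeric(origin), cell_size = cell_size,
                 n_rows = nrow(elevation), n_cols = ncol(elevation),
                 elevation = elevation, land_cover = lc, classes = cls),
            class = "LandscapeRaster")
}

#' @export
print.LandscapeRaster <- function(x, ...) {
  cat("<LandscapeRaster> ", x$n_rows, "x", x$n_cols, " cells @ ",
      x$cell_size, " m, origin (", x$origin[1], ", ", x$origin[2], ")\n",
      sep = "")
  cat("  elevation: ", round(min(x$elevation)), "-", round(max(x$elevation)),
      " m; cover: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

landscape_extent <- function(ls) {
  c(xmin = ls$origin[1], xmax = ls$origin[1] + ls$n_cols * ls$cell_size,
    ymin = ls$origin[2], ymax = ls$origin[2] + ls$n_rows * ls$cell_size)
}

in_landscape <- function(ls, x, y) {
  ext <- landscape_extent(ls)
  x >= ext["xmin"] & x <= ext["xmax"] & y >= ext["ymin"] & y <= ext["ymax"]
}

# separable Gaussian smoothing of a matrix (reflected edges via
# renormalized truncated kernels)
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  smooth_dim <- function(mat, n) {
    out <- matrix(0, nrow(mat), ncol(mat))
    wsum <- numeric(n)
    for (o in -half:half) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n) # clamp at edges
      out <- out + k[o + half + 1L] * mat[idx, , drop = FALSE]
    }
    out / sum(k)
  }
  t(smooth_dim(t(smooth_dim(m, nrow(m))), ncol(m)))
}

# elevation-dependent (unnormalized) class weights; t in [0,1] runs from the
# valley floor to the top of the gradient. Urban/arable/water load the low
# end, mosaic (and to a lesser degree grassland/forest) the high end.
class_weights <- function(t) {
  cbind(arable    = 2.0 * (1 - t)^2 + 0.20,
        grassland = 1.1 * exp(-((t - 0.45) / 0.30)^2) + 0.20,
        forest    = 0.55 + 0.85 * exp(-((t - 0.65) / 0.30)^2),
        urban     = 1.6 * (1 - t)^3 + 0.05,
        water     = 0.55 * (1 - t)^3 + 0.02,
        mosaic    = 2.3 * t^2 + 0.05)
}

# one pass of a 3x3 modal filter over an integer class grid; ties keep the
# cell's current class, then fall back to the lowest class code.
modal_smooth <- function(lc, n_classes) {
  nr <- nrow(lc); nc <- ncol(lc)
  counts <- array(0L, c(nr, nc, n_classes))
  for (di in -1:1) for (dj in -1:1) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    shifted <- lc[ri, cj, drop = FALSE]
    for (k in seq_len(n_classes))
      counts[, , k] <- counts[, , k] + (shifted == k)
  }
  best <- matrix(1L, nr, nc); bestn <- counts[, , 1]
  for (k in 2:n_classes) {
    better <- counts[, , k] > bestn
    best[better] <- k; bestn[better] <- counts[, , k][better]
  }
  # ties: keep current class when it attains the max count
  cur <- matrix(0L, nr, nc)
  for (k in seq_len(n_classes)) cur[lc == k] <- counts[, , k][lc == k]
  keep <- cur == bestn
  best[keep] <- lc[keep]
  best
}

#' Generate a synthetic landscape
#'
#' Builds an elevation grid as a linear south-to-north gradient plus smoothed
#' Gaussian noise, then draws a land-cover class per cell from
#' elevation-dependent class probabilities and applies modal smoothing to
#' create contiguous patches. The construction emulates a study area whose
#' habitats are distributed along an elevation gradient: arable and urban
#' cover dominate the lowlands, pasture/mosaic cultivation the higher ground,
#' so that nests placed across the gradient fall into several distinguishable
#' natal habitat types.
#'
#' @param n_rows,n_cols Grid size in cells (each at least 50).
#' @param cell_size Cell edge length, meters.
#' @param origin Lower-left corner `(x0, y0)`, meters.
#' @param elev_range Elevation range `(min, max)` in meters spanned by the
#'   gradient at `gradient = 1`.
#' @param gradient Gradient strength in `[0, 1]`-ish scale; 0 gives a flat
#'   expected elevation and a spatially homogeneous class mixture.
#' @param noise_sd SD (meters) of the smoothed elevation noise.
#' @param noise_sigma Smoothing length of the noise, in cells.
#' @param mixing Class-mixing temperature; larger values flatten the class
#'   probabilities (more interspersion), smaller values sharpen them.
#' @param smooth_passes Number of 3x3 modal-smoothing passes applied to the
#'   sampled cover grid.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   landscape bit for bit.
#' @return A [landscape_raster()] object.
#' @export
generate_landscape <- function(n_rows = 120, n_cols = 120, cell_size = 100,
                               origin = c(0, 0), elev_range = c(500, 1100),
                               gradient = 1, noise_sd = 25, noise_sigma = 2,
                               mixing = 1, smooth_passes = 2, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_rows < 50 || n_cols < 50)
    stop("grid must be at least 50x50 cells (got ", n_rows, "x", n_cols, ")")
  if (mixing <= 0) stop("mixing must be positive")
  set.seed(seed)

  mid <- mean(elev_range); halfspan <- diff(elev_range) / 2
  trow <- (seq_len(n_rows) - 0.5) / n_rows          # 0..1 south -> north
  base <- mid + gradient * halfspan * (2 * trow - 1) # expected elevation
  elev <- matrix(base, n_rows, n_cols)
  if (noise_sd > 0) {
    noise <- gauss_smooth(matrix(rnorm(n_rows * n_cols), n_rows, n_cols),
                          noise_sigma)
    noise <- noise / sd(noise) * noise_sd
    elev <- elev + noise
  }

  # class probabilities follow the EXPECTED elevation so gradient = 0 yields
  # a homogeneous mixture
  tcl <- if (gradient > 0) trow else rep(0.5, n_rows)
  w <- class_weights(tcl)^(1 / mixing)
  p <- w / rowSums(w)
  lc <- matrix(0L, n_rows, n_cols)
  for (i in seq_len(n_rows))
    lc[i, ] <- sample.int(ncol(p), n_cols, replace = TRUE, prob = p[i, ])
  for (s in seq_len(smooth_passes)) lc <- modal_smooth(lc, ncol(p))

  landscape_raster(elev, lc, origin = origin, cell_size = cell_size)
}

#' Place nests across the elevation gradient
#'
#' Samples nest locations stratified over the landscape's elevation gradient
#' (one band of rows per nest, cycling), at least `spacing_min` apart and at
#' least `edge_buffer` from the raster edge so the natal territory buffer is
#' fully supported.
#'
#' @param landscape A [landscape_raster()] object.
#' @param n_individuals Number of nests to place.
#' @param spacing_min Minimum pairwise nest distance, meters.
#' @param edge_buffer Minimum distance from the raster edge, meters
#'   (default the 2 km territory radius).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling attempts per nest.
#' @return data.frame with columns `id`, `x`, `y`, `year`.
#' @export
place_nests <- function(landscape, n_individuals, spacing_min = 2000,
                        edge_buffer = 2000, seed, max_tries = 500) {
  if (missing(seed)) stop("seed is required")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(seed)
  ext <- landscape_extent(landscape)
  xr <- c(ext["xmin"] + edge_buffer, ext["xmax"] - edge_buffer)
  yr <- c(ext["ymin"] + edge_buffer, ext["ymax"] - edge_buffer)
  if (xr[1] >= xr[2] || yr[1] >= yr[2])
    stop("raster too small for the requested edge buffer")

  # stratify the usable y-range into n bands, cycle through them
  bands <- seq(yr[1], yr[2], length.out = n_individuals + 1L)
  xs <- ys <- numeric(0)
  for (i in seq_len(n_individuals)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, xr[1], xr[2])
      y <- runif(1, bands[i], bands[i + 1L])
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= spacing_min^2)) {
        xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not satisfy spacing_min = ", spacing_min, " within the ",
           "raster; placed ", length(xs), " of ", n_individuals, " nests")
  }
  data.frame(id = sprintf("ind%02d", seq_len(n_individuals)),
             x = xs, y = ys, year = 1L, stringsAsFactors = FALSE)
}

#' Write / read a grid in ESRI ASCII format
#'
#' Plain-text raster exchange: a 6-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, top row first. Used for both the elevation band (numeric) and the
#' land-cover band (integer codes).
#'
#' @param m Matrix in the package's bottom-up row order.
#' @param path Output file.
#' @param origin,cell_size Grid registration (see [landscape_raster()]).
#' @export
write_ascii_grid <- function(m, path, origin = c(0, 0), cell_size = 100) {
  hdr <- c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
           paste("xllcorner", origin[1]), paste("yllcorner", origin[2]),
           paste("cellsize", cell_size), "NODATA_value -9999")
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1L,
                paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()`: list with `matrix`, `origin`, `cell_size`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  hv <- setNames(as.numeric(vapply(hdr, `[`, "", 2L)),
                 vapply(hdr, `[`, "", 1L))
  nc <- as.integer(hv[["ncols"]]); nr <- as.integer(hv[["nrows"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE] # back to bottom-up order
  list(matrix = m, origin = c(hv[["xllcorner"]], hv[["yllcorner"]]),
       cell_size = hv[["cellsize"]])
}

#' Read a landscape from paired ASCII grids
#'
#' @param elevation_path,cover_path Paths to the elevation and land-cover
#'   grids (ESRI ASCII). The two grids must match in shape and registration.
#' @param class_codes Optional named integer vector mapping the cover file's
#'   codes to the package vocabulary, e.g. `c(arable = 10, ...)`; by default
#'   codes 1-6 in [nhpi_classes()] order.
#' @return A [landscape_raster()] object.
#' @export
read_raster <- function(elevation_path, cover_path, class_codes = NULL) {
  e <- read_ascii_grid(elevation_path)
  l <- read_ascii_grid(cover_path)
  if (!all(dim(e$matrix) == dim(l$matrix)))
    stop("elevation and land-cover grids differ in shape")
  if (any(abs(e$origin - l$origin) > 1e-6) ||
      abs(e$cell_size - l$cell_size) > 1e-9)
    stop("elevation and land-cover grids differ in registration")
  lc <- l$matrix
  if (!is.null(class_codes)) {
    cls <- nhpi_classes()
    if (!all(cls %in% names(class_codes)))
      stop("class_codes must name all of: ", paste(cls, collapse = ", "))
    rec <- match(lc, class_codes[cls])
    if (any(is.na(rec) & !is.na(lc)))
      stop("land-cover code(s) outside the class table: ",
           paste(unique(lc[is.na(rec)]), collapse = ", "))
    lc <- matrix(rec, nrow(lc), ncol(lc))
  }
  bad <- setdiff(unique(as.vector(lc)), seq_along(nhpi_classes()))
  if (length(bad))
    stop("unknown land-cover code(s): ", paste(bad, collapse = ", "))
  landscape_raster(e$matrix, lc, origin = e$origin, cell_size = e$cell_size)
}

#' Write a landscape as paired ASCII grids
#'
#' @param landscape A [landscape_raster()] object.
#' @param elevation_path,cover_path Output paths.
#' @export
write_raster <- function(landscape, elevation_path, cover_path) {
  write_ascii_grid(landscape$elevation, elevation_path,
                   landscape$origin, landscape$cell_size)
  write_ascii_grid(landscape$land_cover, cover_path,
                   landscape$origin, landscape$cell_size)
  invisible(c(elevation_path, cover_path))
}
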