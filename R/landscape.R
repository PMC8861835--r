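#' Synthetic landscape grids
#'
#' A `landscape` is a lightweight raster stack: a set of named numeric
#' matrices sharing one 30-m (by default) grid, indexed row = y (south to
#' north), column = x (west to east). Cell (1, 1) has its centre at
#' `origin + resolution/2`.
#'
#' @name landscape
NULL

#' Generate a spatially autocorrelated synthetic landscape
#'
#' Builds the covariate layers used throughout the workflow: elevation (m),
#' a three-class escape-cover grid (1 = open, 2 = shrub > 0.5 m, 3 = tree),
#' fractional shrub height, bare ground, herbaceous and sage height layers
#' in \[0, 1\], Euclidean distance-to-feature layers (roads, aspen, forest)
#' and habitat-based occurrence surfaces for mountain lions and their kill
#' sites (`indirect_lion`, `indirect_kill`, both in \[0, 1\]).
#'
#' Continuous layers are smoothed Gaussian white noise: a latent field is
#' convolved with a Gaussian kernel of standard deviation `smoothness`
#' cells, so `smoothness = 0` returns white noise. Cover classes are
#' derived by thresholding a latent field, then cells classified shrub
#' whose shrub-height fraction is at or below 0.5 (on the 0-1 scale,
#' standing in for 0.5 m of a 1-m maximum) are reclassified open, since
#' such shrubs cannot conceal a coyote. Distance layers are exact Euclidean
#' distances from cell centres to sampled feature masks (roads: random
#' transects; aspen/forest: patches of the tree class), 0 inside a feature.
#'
#' @param seed integer RNG seed; the same seed and arguments give
#'   bit-identical landscapes.
#' @param extent number of cells per axis, either one integer (square) or
#'   `c(nx, ny)`; at least 32.
#' @param resolution cell size in metres (> 0), default 30.
#' @param smoothness Gaussian kernel sd in cells controlling spatial
#'   autocorrelation; 0 gives white noise.
#' @return An object of class `landscape`: list with `origin`, `resolution`,
#'   `nx`, `ny` and `layers` (named list of `ny x nx` matrices).
#' @export
gen_landscape <- function(seed, extent = 128, resolution = 30, smoothness = 4) {
  if (!is.finite(resolution) || resolution <= 0)
    stop("`resolution` must be a positive number")
  extent <- as.integer(rep(extent, length.out = 2L))
  if (any(extent < 32L)) stop("`extent` must be at least 32 cells per axis")
  nx <- extent[1L]; ny <- extent[2L]

  rng <- local_rng(seed)
  field <- function() smooth_field(matrix(rng$norm(nx * ny), ny, nx), smoothness)

  elev_z <- field()
  layers <- list(
    elev = 2200 + 250 * elev_z,
    shrub_height = stats::pnorm(field()),
    bare_ground  = stats::pnorm(field()),
    herb         = stats::pnorm(field()),
    sage_height  = stats::pnorm(field())
  )

  # cover from a latent field: top decile tree, next three deciles shrub
  lat <- field()
  qs <- stats::quantile(lat, c(0.6, 0.9))
  cover <- matrix(1L, ny, nx)
  cover[lat > qs[1L]] <- 2L
  cover[lat > qs[2L]] <- 3L
  cover[cover == 2L & layers$shrub_height <= 0.5] <- 1L
  layers$cover <- cover

  # feature masks: roads as straight transects, aspen as a random subset of
  # tree patches, forest as the tree class itself
  road_mask <- matrix(FALSE, ny, nx)
  for (k in seq_len(2L)) {
    if (rng$unif(1) < 0.5) {
      road_mask[max(1L, min(ny, round(rng$unif(1) * ny))), ] <- TRUE
    } else {
      road_mask[, max(1L, min(nx, round(rng$unif(1) * nx)))] <- TRUE
    }
  }
  tree_mask <- cover == 3L
  if (!any(tree_mask)) tree_mask[sample_cells(rng, ny, nx, 5L)] <- TRUE
  aspen_mask <- tree_mask & matrix(rng$unif(nx * ny) < 0.3, ny, nx)
  if (!any(aspen_mask)) aspen_mask[which(tree_mask)[1L]] <- TRUE

  layers$dist_road   <- distance_to_mask(road_mask, resolution)
  layers$dist_aspen  <- distance_to_mask(aspen_mask, resolution)
  layers$dist_forest <- distance_to_mask(tree_mask, resolution)

  # habitat-based occurrence surfaces (indirect risk/reward); rescaled [0, 1]
  layers$indirect_lion <- rescale01(smooth_field(matrix(rng$norm(nx * ny), ny, nx),
                                                 max(smoothness, 1)))
  layers$indirect_kill <- rescale01(smooth_field(matrix(rng$norm(nx * ny), ny, nx),
                                                 max(smoothness, 1)))

  structure(
    list(origin = c(x = 0, y = 0), resolution = resolution,
         nx = nx, ny = ny, layers = layers),
    class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells at %g m; layers: %s\n",
              x$nx, x$ny, x$resolution, paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# deterministic RNG stream isolated from the global seed state
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) function(n, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(n, ...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = draw(stats::rnorm), unif = draw(stats::runif),
       gamma = draw(stats::rgamma), pois = draw(stats::rpois),
       exp = draw(stats::rexp), sample_int = draw(function(n, size, prob = NULL)
         sample.int(n, size, replace = TRUE, prob = prob)))
}

sample_cells <- function(rng, ny, nx, k) {
  cbind(pmax(1L, ceiling(rng$unif(k) * ny)), pmax(1L, ceiling(rng$unif(k) * nx)))
}

# separable Gaussian blur; sd in cells, truncated at 3 sd
smooth_field <- function(z, sd_cells) {
  if (sd_cells <= 0) return(scale_field(z))
  half <- max(1L, ceiling(3 * sd_cells))
  w <- stats::dnorm(seq(-half, half), sd = sd_cells)
  w <- w / sum(w)
  K <- function(n) {
    m <- matrix(0, n, n)
    for (i in seq_len(n)) {
      idx <- i + seq(-half, half)
      ok <- idx >= 1L & idx <= n
      m[i, idx[ok]] <- w[ok] / sum(w[ok])
    }
    m
  }
  scale_field(K(nrow(z)) %*% z %*% t(K(ncol(z))))
}

scale_field <- function(z) (z - mean(z)) / stats::sd(z)

rescale01 <- function(z) (z - min(z)) / (max(z) - min(z))

# exact Euclidean distance (m) from every cell centre to the nearest TRUE
# cell, via the separable squared-distance transform (lower envelope of
# parabolas per row then per column); 0 inside the feature
distance_to_mask <- function(mask, resolution) {
  ny <- nrow(mask); nx <- ncol(mask)
  if (!any(mask)) return(matrix(Inf, ny, nx))
  f <- matrix(ifelse(mask, 0, Inf), ny, nx)
  g <- apply(f, 2L, dt_1d)          # along rows (y) within each column
  d2 <- t(apply(g, 1L, dt_1d))      # along columns (x) within each row
  sqrt(d2) * resolution
}

# 1-d squared distance transform: d[i] = min_j (i-j)^2 + f[j], over finite f[j]
dt_1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(rep(Inf, n))
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in fin[-1L]) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n)
  k0 <- 1L
  for (q in seq_len(n)) {
    while (z[k0 + 1L] < q) k0 <- k0 + 1L
    d[q] <- (q - v[k0])^2 + f[v[k0]]
  }
  d
}

#' Extract layer values at projected coordinates
#'
#' Nearest-cell lookup. Coordinates outside the landscape return `NA`.
#'
#' @param land a [landscape][gen_landscape] object.
#' @param layer layer name.
#' @param x,y numeric vectors of projected coordinates (m).
#' @return numeric vector of cell values.
#' @export
extract_layer <- function(land, layer, x, y) {
  lay <- land$layers[[layer]]
  if (is.null(lay)) stop(sprintf("unknown layer '%s'", layer))
  ij <- coord_to_cell(land, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(ij[, 1L])
  out[ok] <- lay[cbind(ij[ok, 1L], ij[ok, 2L])]
  out
}

coord_to_cell <- function(land, x, y) {
  col <- floor((x - land$origin[["x"]]) / land$resolution) + 1L
  row <- floor((y - land$origin[["y"]]) / land$resolution) + 1L
  bad <- !is.finite(col) | !is.finite(row) | col < 1L | col > land$nx | row < 1L | row > land$ny
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Test whether points fall inside the landscape extent
#' @inheritParams extract_layer
#' @return logical vector.
#' @export
in_landscape <- function(land, x, y) {
  x >= land$origin[["x"]] & x < land$origin[["x"]] + land$nx * land$resolution &
    y >= land$origin[["y"]] & y < land$origin[["y"]] + land$ny * land$resolution
}

#' Write / read a landscape layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange (a standard GIS format readable by QGIS,
#' GDAL and most R spatial stacks). One file per layer.
#'
#' @param land a landscape.
#' @param layer layer name.
#' @param path output file.
#' @export
write_ascii_grid <- function(land, layer, path) {
  lay <- land$layers[[layer]]
  if (is.null(lay)) stop(sprintf("unknown layer '%s'", layer))
  hdr <- c(
    sprintf("ncols %d", land$nx),
    sprintf("nrows %d", land$ny),
    sprintf("xllcorner %.6f", land$origin[["x"]]),
    sprintf("yllcorner %.6f", land$origin[["y"]]),
    sprintf("cellsize %.6f", land$resolution),
    "NODATA_value -9999")
  body <- apply(lay[rev(seq_len(land$ny)), , drop = FALSE], 1L,
                function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid` returns a single-layer landscape.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) as.numeric(sub(paste0("^", key, "\\s+"), "", hdr[grepl(paste0("^", key), hdr, ignore.case = TRUE)]))
  nx <- as.integer(val("ncols")); ny <- as.integer(val("nrows"))
  m <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE),
              ny, nx, byrow = TRUE)
  structure(
    list(origin = c(x = val("xllcorner"), y = val("yllcorner")),
         resolution = val("cellsize"), nx = nx, ny = ny,
         layers = list(layer = m[rev(seq_len(ny)), , drop = FALSE])),
    class = "landscape")
}
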