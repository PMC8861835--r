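#' Terrain Ruggedness Index
#'
#' Per cell, the square root of the sum of squared elevation differences
#' between the cell and its eight neighbours (Riley et al. 1999). Edge
#' cells use the neighbours that exist.
#'
#' @param elev elevation matrix (>= 3 x 3).
#' @return matrix of TRI values (>= 0).
#' @export
compute_tri <- function(elev) {
  if (all(is.na(elev))) stop("elevation grid is all missing")
  if (nrow(elev) < 3L || ncol(elev) < 3L) stop("grid must be at least 3 x 3")
  acc <- matrix(0, nrow(elev), ncol(elev))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- shift_mat(elev, dy, dx)
    d <- (elev - nb)^2
    d[is.na(d)] <- 0
    acc <- acc + d
  }
  sqrt(acc)
}

#' Topographic Position Index
#'
#' Cell elevation minus the mean elevation of the surrounding
#' `window_cells` x `window_cells` window, excluding the cell itself
#' (De Reu et al. 2013). Edge cells use the part of the window that exists.
#'
#' @param elev elevation matrix.
#' @param window_cells odd window size >= 3 (default 3).
#' @return matrix of TPI values.
#' @export
compute_tpi <- function(elev, window_cells = 3L) {
  if (window_cells < 3L) stop("`window_cells` must be at least 3")
  if (window_cells %% 2L == 0L) stop("`window_cells` must be odd")
  half <- (window_cells - 1L) %/% 2L
  s <- matrix(0, nrow(elev), ncol(elev))
  n <- matrix(0, nrow(elev), ncol(elev))
  for (dy in -half:half) for (dx in -half:half) {
    if (dy == 0L && dx == 0L) next
    nb <- shift_mat(elev, dy, dx)
    ok <- !is.na(nb)
    s[ok] <- s[ok] + nb[ok]
    n <- n + ok
  }
  elev - s / n
}

# shift a matrix by (dy, dx) cells, padding with NA
shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
  oky <- ys >= 1L & ys <= ny; okx <- xs >= 1L & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Add derived terrain layers to a landscape
#'
#' Computes `tri` and `tpi` from the `elev` layer and stores them as
#' additional layers.
#'
#' @param land a landscape with an `elev` layer.
#' @param tpi_window odd TPI window size.
#' @return the landscape with `tri` and `tpi` layers added.
#' @export
add_terrain_layers <- function(land, tpi_window = 3L) {
  land$layers$tri <- compute_tri(land$layers$elev)
  land$layers$tpi <- compute_tpi(land$layers$elev, tpi_window)
  land
}

#' Escape-cover proportions within a circular buffer
#'
#' Fraction of cells of each cover class (open / shrub > 0.5 m / tree)
#' whose centre lies within a disc of the given diameter around each
#' point. The default 256-m diameter is half the average coyote step
#' length. If the buffer is smaller than one cell the single containing
#' cell's class is returned as an indicator.
#'
#' @param land a landscape with a `cover` layer (1 open, 2 shrub, 3 tree).
#' @param x,y point coordinates (m); must be inside the landscape.
#' @param buffer_diameter_m buffer diameter in metres (default 256).
#' @return matrix with columns `open`, `shrub`, `tree`; rows sum to 1.
#' @export
cover_proportions <- function(land, x, y, buffer_diameter_m = 256) {
  if (any(!in_landscape(land, x, y))) stop("points must lie inside the landscape")
  cov <- land$layers$cover
  radius_cells <- (buffer_diameter_m / 2) / land$resolution
  half <- floor(radius_cells)
  offs <- expand.grid(dy = -half:half, dx = -half:half)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius_cells^2, , drop = FALSE]
  if (nrow(offs) == 0L) offs <- data.frame(dy = 0L, dx = 0L)
  ij <- coord_to_cell(land, x, y)
  out <- matrix(0, length(x), 3L, dimnames = list(NULL, c("open", "shrub", "tree")))
  for (p in seq_along(x)) {
    rows <- ij[p, 1L] + offs$dy; cols <- ij[p, 2L] + offs$dx
    ok <- rows >= 1L & rows <= land$ny & cols >= 1L & cols <= land$nx
    cls <- cov[cbind(rows[ok], cols[ok])]
    out[p, ] <- tabulate(cls, 3L) / length(cls)
  }
  out
}

#' Centre and scale covariate columns
#'
#' Subtracts the mean and divides by the (n-1 denominator) standard
#' deviation of each named column, recording the scaling so it can be
#' inverted or applied to new data.
#'
#' @param table data frame.
#' @param columns character vector of columns to standardize.
#' @return list with `data` (transformed table) and `scaling` (data frame
#'   `column, mean, sd`).
#' @export
standardize <- function(table, columns) {
  mu <- vapply(columns, function(cn) mean(table[[cn]], na.rm = TRUE), 0)
  sd_ <- vapply(columns, function(cn) stats::sd(table[[cn]], na.rm = TRUE), 0)
  bad <- columns[!is.finite(sd_) | sd_ == 0]
  if (length(bad))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  for (i in seq_along(columns))
    table[[columns[i]]] <- (table[[columns[i]]] - mu[i]) / sd_[i]
  list(data = table,
       scaling = data.frame(column = columns, mean = unname(mu), sd = unname(sd_)))
}

#' Invert or re-apply a standardization
#'
#' @param table data frame of standardized columns.
#' @param scaling scaling record from [standardize()].
#' @param inverse if `TRUE` (default) undo the transform; if `FALSE` apply it.
#' @return transformed data frame.
#' @export
apply_scaling <- function(table, scaling, inverse = TRUE) {
  for (i in seq_len(nrow(scaling))) {
    cn <- scaling$column[i]
    if (!cn %in% names(table)) next
    table[[cn]] <- if (inverse) table[[cn]] * scaling$sd[i] + scaling$mean[i]
                   else (table[[cn]] - scaling$mean[i]) / scaling$sd[i]
  }
  table
}

#' Iterative VIF-based multicollinearity pruning
#'
#' Computes the variance inflation factor VIF_j = 1 / (1 - R^2_j) of each
#' column regressed on the others and repeatedly removes the highest-VIF
#' column while any VIF is at or above the threshold (< 3 retained, the
#' conventional screen). Perfectly collinear columns get infinite VIF and
#' are removed first; ties break toward the earlier column in table order.
#'
#' @param design data frame of numeric candidate covariates (rows > columns).
#' @param threshold VIF threshold (default 3).
#' @return list with `retained` (character), `removed` (data frame
#'   `column, vif, step`) and `vif` (final VIFs).
#' @export
vif_prune <- function(design, threshold = 3) {
  cols <- names(design)
  if (length(cols) < 2L) stop("need at least 2 columns")
  if (nrow(design) <= length(cols)) stop("need more rows than columns")
  removed <- data.frame(column = character(0), vif = numeric(0), step = integer(0))
  step <- 0L
  repeat {
    if (length(cols) < 2L) break
    v <- vapply(cols, function(cn) {
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(setdiff(cols, cn), cn), data = design))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    if (max(v) < threshold) break
    step <- step + 1L
    drop_i <- which.max(v)  # first max in table order on ties
    removed <- rbind(removed, data.frame(column = cols[drop_i],
                                         vif = unname(v[drop_i]), step = step))
    cols <- cols[-drop_i]
  }
  final <- if (length(cols) >= 2L) {
    vapply(cols, function(cn) {
      r2 <- suppressWarnings(summary(stats::lm(
        stats::reformulate(setdiff(cols, cn), cn), data = design))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
  } else stats::setNames(rep(1, length(cols)), cols)
  list(retained = cols, removed = removed, vif = final)
}

#' ROC threshold maximizing sensitivity at a bounded false-positive rate
#'
#' Among candidate thresholds (classify positive when `score >= threshold`)
#' with false-positive rate at most `max_fpr`, returns the one with maximal
#' sensitivity; ties break toward the lower threshold so future
#' classifications stay as sensitive as possible. If no threshold
#' satisfies the constraint a threshold above the maximum score is
#' returned with a warning (nothing classified positive).
#'
#' @param scores numeric classifier scores.
#' @param labels 0/1 (or logical) true classes; both classes must be present.
#' @param max_fpr maximum false-positive rate (default 0.05).
#' @return list with `threshold`, `sensitivity`, `fpr`.
#' @export
roc_cutoff <- function(scores, labels, max_fpr = 0.05) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels == 1L] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0L] >= t), 0)
  ok <- fpr <= max_fpr
  if (!any(ok)) {
    warning("no threshold satisfies the false-positive constraint")
    t_out <- max(scores) + 1
    return(list(threshold = t_out, sensitivity = 0, fpr = 0))
  }
  best <- which(ok & sens == max(sens[ok]))
  pick <- best[which.min(thr[best])]
  list(threshold = thr[pick], sensitivity = sens[pick], fpr = fpr[pick])
}

#' Fit a habitat-based occurrence surface from used and available points
#'
#' A probability random forest on the landscape covariates classifies used
#' versus available points; predictions over the whole grid give a relative
#' probability-of-occurrence surface in \[0, 1\]. This is the internal,
#' fully testable route to the indirect risk/reward layers; externally
#' supplied rasters can be used instead (see `provenance`).
#'
#' @param used_xy,available_xy two-column matrices / data frames of
#'   coordinates (>= 20 points each).
#' @param land a landscape; covariates are its numeric layers.
#' @param seed RNG seed for the forest.
#' @param layers character vector of predictor layer names (default: the
#'   terrain and fractional layers).
#' @param num_trees forest size.
#' @return a single-layer landscape whose `layers$occurrence` holds the
#'   surface, with attribute `provenance = "internal_classifier"`.
#' @export
fit_occurrence_surface <- function(used_xy, available_xy, land, seed = 1,
                                   layers = c("elev", "shrub_height",
                                              "bare_ground", "herb",
                                              "sage_height"),
                                   num_trees = 300) {
  used_xy <- as.matrix(used_xy); available_xy <- as.matrix(available_xy)
  if (nrow(used_xy) < 20L || nrow(available_xy) < 20L)
    stop("need at least 20 used and 20 available points")
  pts <- rbind(used_xy, available_xy)
  lab <- factor(rep(c("used", "avail"), c(nrow(used_xy), nrow(available_xy))),
                levels = c("avail", "used"))
  covs <- as.data.frame(lapply(layers, function(nm)
    extract_layer(land, nm, pts[, 1L], pts[, 2L])))
  names(covs) <- layers
  keep <- stats::complete.cases(covs)
  if (length(unique(lab[keep])) < 2L) stop("degenerate classes after extraction")
  fit <- ranger::ranger(x = covs[keep, , drop = FALSE], y = lab[keep],
                        probability = TRUE, num.trees = num_trees,
                        seed = as.integer(seed) %% .Machine$integer.max,
                        num.threads = 1L)
  grid <- as.data.frame(lapply(layers, function(nm) as.vector(land$layers[[nm]])))
  names(grid) <- layers
  pred <- stats::predict(fit, data = grid, num.threads = 1L)$predictions[, "used"]
  surf <- matrix(pred, land$ny, land$nx)
  out <- land
  out$layers <- list(occurrence = surf)
  attr(out, "provenance") <- "internal_classifier"
  out
}
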