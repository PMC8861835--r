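#' Exact annulus areas for the ten concentric kill-site rings
#'
#' Ring k is the annulus (100(k-1), 100k\] m; the areas sum exactly to the
#' area of the 1000-m disc.
#'
#' @param n_rings number of rings (default 10).
#' @param ring_width_m ring width (default 100 m).
#' @return numeric vector of areas (m^2).
#' @export
ring_areas <- function(n_rings = 10L, ring_width_m = 100) {
  r_out <- seq_len(n_rings) * ring_width_m
  r_in <- r_out - ring_width_m
  pi * (r_out^2 - r_in^2)
}

#' Screen kill sites for coyote accessibility
#'
#' A kill enters the pre (post) model only if at least one coyote fix lies
#' within 1000 m (inclusive boundary) during the 14 days before (after)
#' the first lion location at the kill.
#'
#' @param kills kill data frame (`id, x, y, t_first, t_last`).
#' @param coyote_fixes pooled coyote fix data frame.
#' @param radius_m eligibility radius (default 1000).
#' @param window_days window length (default 14).
#' @return `kills` with logical columns `pre_eligible`, `post_eligible`.
#' @export
eligibility_filter <- function(kills, coyote_fixes, radius_m = 1000,
                               window_days = 14) {
  pre <- post <- logical(nrow(kills))
  for (i in seq_len(nrow(kills))) {
    d <- euclid(kills$x[i], kills$y[i], coyote_fixes$x, coyote_fixes$y)
    near <- d <= radius_m
    dt <- days_between(kills$t_first[i], coyote_fixes$t)
    pre[i] <- any(near & dt >= -window_days & dt < 0)
    post[i] <- any(near & dt >= 0 & dt < window_days)
  }
  kills$pre_eligible <- pre
  kills$post_eligible <- post
  kills
}

#' Classify daily ring use around one kill site
#'
#' One record per (ring, day): rings are upper-inclusive annuli
#' (100(k-1), 100k\] m (a fix at exactly 100.0 m falls in ring 1; a fix at
#' the kill itself falls in ring 1), and day bins are 24-h intervals from
#' the first lion location — post-kill day d covers
#' \[(d-1), d) x 24 h after `t_first`, pre-kill day -d the mirror-image
#' interval before it. A ring-day is used when at least one coyote fix
#' falls in it.
#'
#' @param kill one-row kill data frame.
#' @param coyote_fixes pooled coyote fixes.
#' @param side `"pre"` or `"post"`.
#' @param n_rings,ring_width_m,window_days ring/window geometry.
#' @return data frame `kill_id, ring, day, used, ring_area, dist_m`
#'   (`dist_m` is the ring midpoint distance used as the model covariate).
#' @export
classify_use <- function(kill, coyote_fixes, side = c("post", "pre"),
                         n_rings = 10L, ring_width_m = 100,
                         window_days = 14) {
  side <- match.arg(side)
  d <- euclid(kill$x, kill$y, coyote_fixes$x, coyote_fixes$y)
  dt_days <- days_between(kill$t_first, coyote_fixes$t)
  ring <- pmax(1L, ceiling(d / ring_width_m))
  day <- if (side == "post") floor(dt_days) + 1L else floor(dt_days)
  sel <- ring <= n_rings &
    (if (side == "post") dt_days >= 0 & dt_days < window_days
     else dt_days < 0 & dt_days >= -window_days)
  used_keys <- unique(paste(ring[sel], day[sel]))
  grid <- expand.grid(ring = seq_len(n_rings),
                      day = if (side == "post") seq_len(window_days)
                            else -seq_len(window_days))
  areas <- ring_areas(n_rings, ring_width_m)
  data.frame(
    kill_id = kill$id,
    ring = grid$ring, day = grid$day,
    used = paste(grid$ring, grid$day) %in% used_keys,
    ring_area = areas[grid$ring],
    dist_m = (grid$ring - 0.5) * ring_width_m)
}

#' Fix-rate-adjusted local coyote intensity around a kill
#'
#' Count of coyote fixes within `radius_m` over the window, divided by the
#' collar fix rate, accounting for sampling variation in apparent use.
#'
#' @param kill one-row kill data frame.
#' @param coyote_fixes pooled coyote fixes.
#' @param fix_rate obtained/expected fix fraction in (0, 1].
#' @param side `"pre"` or `"post"`.
#' @param radius_m count radius (default 2500).
#' @param window_days window length.
#' @return adjusted count (numeric).
#' @export
local_intensity <- function(kill, coyote_fixes, fix_rate, side = c("post", "pre"),
                            radius_m = 2500, window_days = 14) {
  side <- match.arg(side)
  if (fix_rate <= 0) stop("`fix_rate` must be positive")
  d <- euclid(kill$x, kill$y, coyote_fixes$x, coyote_fixes$y)
  dt_days <- days_between(kill$t_first, coyote_fixes$t)
  sel <- d <= radius_m &
    (if (side == "post") dt_days >= 0 & dt_days < window_days
     else dt_days < 0 & dt_days >= -window_days)
  sum(sel) / fix_rate
}

#' Build the full ring-day use table for eligible kills
#'
#' Combines [classify_use()], [local_intensity()], the lion-activity flag
#' (post-kill day d is lion-active while the last lion fix at the kill is
#' later than the start of that day bin) and per-window collar fix rates
#' (obtained/expected hourly fixes of contributing collars, averaged when
#' several coyotes contribute).
#'
#' @param kills kill table with eligibility columns from
#'   [eligibility_filter()].
#' @param coyote_fixes pooled coyote fixes.
#' @param side `"pre"` or `"post"`.
#' @param window_days,n_rings,ring_width_m geometry.
#' @return ring-use record data frame (`kill_id, ring, day, used,
#'   ring_area, dist_m, day_abs, local_count, fix_rate, lion_active`).
#' @export
build_ring_records <- function(kills, coyote_fixes, side = c("post", "pre"),
                               window_days = 14, n_rings = 10L,
                               ring_width_m = 100) {
  side <- match.arg(side)
  elig <- if (side == "post") kills$post_eligible else kills$pre_eligible
  kills <- kills[elig, , drop = FALSE]
  if (nrow(kills) == 0L)
    stop("no eligible kills for the ", side, " window")
  out <- vector("list", nrow(kills))
  for (i in seq_len(nrow(kills))) {
    k <- kills[i, ]
    rec <- classify_use(k, coyote_fixes, side, n_rings, ring_width_m,
                        window_days)
    fr <- window_fix_rate(k, coyote_fixes, side, window_days)
    rec$local_count <- local_intensity(k, coyote_fixes, fr, side,
                                       window_days = window_days)
    rec$fix_rate <- fr
    rec$day_abs <- abs(rec$day)
    rec$lion_active <- if (side == "post") {
      (rec$day - 1) * 86400 < as.numeric(k$t_last) - as.numeric(k$t_first)
    } else TRUE
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# obtained/expected hourly fixes of collars contributing fixes within
# 2500 m of the kill during the window; mean over contributing collars
window_fix_rate <- function(kill, coyote_fixes, side, window_days) {
  dt_days <- days_between(kill$t_first, coyote_fixes$t)
  in_win <- if (side == "post") dt_days >= 0 & dt_days < window_days
            else dt_days < 0 & dt_days >= -window_days
  d <- euclid(kill$x, kill$y, coyote_fixes$x, coyote_fixes$y)
  contrib <- unique(coyote_fixes$animal_id[in_win & d <= 2500])
  if (length(contrib) == 0L) return(1)
  expected <- window_days * 24
  rates <- vapply(contrib, function(a)
    sum(in_win & coyote_fixes$animal_id == a) / expected, 0)
  min(1, mean(rates))
}

#' Fit the pre- or post-kill probability-of-use model
#'
#' Binomial penalized model of ring-day use: smooths of day and distance
#' from the kill, the fix-rate-adjusted local coyote count, offsets for
#' the ring area and the inverse collar fix rate (as logs), and a random
#' intercept per kill site. In the post-kill model the lion-activity flag
#' is passed through backwards AIC elimination.
#'
#' @param records ring-use table from [build_ring_records()].
#' @param side `"pre"` or `"post"`.
#' @param k_day,k_dist basis dimensions.
#' @param method smoothing criterion.
#' @return list with `fit` (`pgam_fit`), `elimination` (backwards-AIC log,
#'   post model only).
#' @export
fit_killsite_model <- function(records, side = c("post", "pre"), k_day = 8,
                               k_dist = 8, method = "GCV.Cp") {
  side <- match.arg(side)
  if (length(unique(records$kill_id)) < 5L)
    stop("need at least 5 eligible kills")
  records$inv_fix_rate <- 1 / records$fix_rate
  records$usedN <- as.integer(records$used)
  records$lion_active_n <- as.integer(records$lion_active)
  smooths <- list(list(var = "day_abs", bs = "tp", k = k_day),
                  list(var = "dist_m", bs = "tp", k = k_dist))
  if (side == "post" && length(unique(records$lion_active_n)) > 1L) {
    ba <- backwards_aic(records, "usedN", smooths,
                        linear = c("local_count", "lion_active_n"),
                        removable = "lion_active_n",
                        offsets = c("ring_area", "inv_fix_rate"),
                        family = "binomial", random = "kill_id",
                        method = method)
    list(fit = ba$fit, elimination = ba$log, retained = ba$retained)
  } else {
    fit <- fit_pgam(records, "usedN", smooths, linear = "local_count",
                    offsets = c("ring_area", "inv_fix_rate"),
                    family = "binomial", random = "kill_id", method = method)
    list(fit = fit, elimination = NULL, retained = "local_count")
  }
}
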