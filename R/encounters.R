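#' Detect coyote-lion fix pairs within space-time thresholds
#'
#' Finds every (coyote fix, lion fix) pair occurring within `dist_km` and
#' `dt_h` of one another (inclusive thresholds: d <= 1 km and |dt| <= 2 h
#' by default), using a time-sorted sweep that equals the brute-force
#' double loop exactly.
#'
#' @param coyote_track,lion_track fix data frames (single animal each).
#' @param dist_km distance threshold, km.
#' @param dt_h time threshold, hours.
#' @return data frame of qualifying pairs: `coyote_id, lion_id, t_coyote,
#'   t_lion, dist_m, dt_h`.
#' @export
detect_encounters <- function(coyote_track, lion_track, dist_km = 1, dt_h = 2) {
  empty <- data.frame(coyote_id = character(0), lion_id = character(0),
                      t_coyote = as.POSIXct(character(0), tz = "UTC"),
                      t_lion = as.POSIXct(character(0), tz = "UTC"),
                      dist_m = numeric(0), dt_h = numeric(0))
  if (nrow(coyote_track) == 0L || nrow(lion_track) == 0L) return(empty)
  lt <- lion_track[order(lion_track$t), , drop = FALSE]
  ltn <- as.numeric(lt$t)
  res <- vector("list", nrow(coyote_track))
  for (i in seq_len(nrow(coyote_track))) {
    tc <- as.numeric(coyote_track$t[i])
    lo <- findInterval(tc - dt_h * 3600, ltn, left.open = TRUE) + 1L
    hi <- findInterval(tc + dt_h * 3600, ltn)
    if (hi < lo) next
    j <- lo:hi
    d <- euclid(coyote_track$x[i], coyote_track$y[i], lt$x[j], lt$y[j])
    ok <- d <= dist_km * 1000
    if (!any(ok)) next
    j <- j[ok]
    res[[i]] <- data.frame(
      coyote_id = coyote_track$animal_id[i], lion_id = lt$animal_id[j],
      t_coyote = coyote_track$t[i], t_lion = lt$t[j],
      dist_m = d[ok], dt_h = (as.numeric(lt$t[j]) - tc) / 3600)
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Merge qualifying fix pairs into encounter bouts
#'
#' Consecutive qualifying coyote fixes of one coyote-lion dyad (no gap
#' larger than the nominal fix interval plus tolerance between them) merge
#' into a single encounter; the encounter starts at the first qualifying
#' coyote fix and ends at the last, and is multi-hour when those differ.
#'
#' @param pairs pair table from [detect_encounters()] (one dyad).
#' @param merge_gap_h largest gap between qualifying coyote fixes kept in
#'   one bout (default 1 h, the nominal interval).
#' @param tolerance_min schedule tolerance, minutes.
#' @return data frame `coyote_id, lion_id, t_start, t_end, n_pairs,
#'   multi_hour`.
#' @export
merge_bouts <- function(pairs, merge_gap_h = 1, tolerance_min = 5) {
  if (nrow(pairs) == 0L)
    return(data.frame(coyote_id = character(0), lion_id = character(0),
                      t_start = as.POSIXct(character(0), tz = "UTC"),
                      t_end = as.POSIXct(character(0), tz = "UTC"),
                      n_pairs = integer(0), multi_hour = logical(0)))
  qt <- sort(unique(pairs$t_coyote))
  gap <- hours_between(qt[-length(qt)], qt[-1L])
  bout <- cumsum(c(0, gap > merge_gap_h + tolerance_min / 60))
  out <- do.call(rbind, lapply(split(seq_along(qt), bout), function(ii) {
    tw <- qt[ii]
    data.frame(coyote_id = pairs$coyote_id[1L], lion_id = pairs$lion_id[1L],
               t_start = min(tw), t_end = max(tw),
               n_pairs = sum(pairs$t_coyote %in% tw),
               multi_hour = max(tw) > min(tw))
  }))
  rownames(out) <- NULL
  out
}

#' Keep encounters separated by an independence gap
#'
#' Within each coyote (pooled over lions), an encounter is dropped when it
#' starts strictly less than `gap_h` hours after the end of the previous
#' retained encounter; one starting exactly `gap_h` later is retained.
#'
#' @param encounters encounter table sorted or not; processed per coyote
#'   in `t_start` order.
#' @param gap_h independence gap, hours (default 5).
#' @return subset of `encounters` with an `independent` flag column added
#'   (all TRUE in the returned subset).
#' @export
filter_independent <- function(encounters, gap_h = 5) {
  if (nrow(encounters) == 0L) {
    encounters$independent <- logical(0)
    return(encounters)
  }
  keep <- logical(nrow(encounters))
  for (cid in unique(encounters$coyote_id)) {
    idx <- which(encounters$coyote_id == cid)
    idx <- idx[order(encounters$t_start[idx])]
    last_end <- NULL
    for (i in idx) {
      if (is.null(last_end) ||
          hours_between(last_end, encounters$t_start[i]) >= gap_h) {
        keep[i] <- TRUE
        last_end <- encounters$t_end[i]
      }
    }
  }
  out <- encounters[keep, , drop = FALSE]
  out$independent <- TRUE
  rownames(out) <- NULL
  out
}

#' Extract pre/post-encounter movement-rate records
#'
#' Hourly movement rates (m/h) from consecutive coyote fixes in the
#' `window_h` hours before the encounter starts and after it ends; fixes
#' during the encounter itself are excluded, since only pre- and
#' post-encounter behaviour is of interest. `time_to_encounter` is the
#' signed hour of the step endpoint: negative relative to `t_start` before
#' the encounter, positive relative to `t_end` after it.
#'
#' @param track coyote fix data frame.
#' @param encounters independent encounter table for that coyote.
#' @param window_h window half-width in hours (5 for the movement-rate
#'   model, 10 for the encounter step-selection model).
#' @param tolerance_min schedule tolerance, minutes.
#' @return data frame `coyote_id, encounter_id, time_to_encounter,
#'   hour_of_day, rate, t`.
#' @export
extract_windows <- function(track, encounters, window_h = 5,
                            tolerance_min = 5) {
  track <- track[order(track$t), , drop = FALSE]
  out <- list()
  for (e in seq_len(nrow(encounters))) {
    enc <- encounters[e, ]
    eid <- sprintf("%s_e%d", enc$coyote_id, e)
    for (side in c("pre", "post")) {
      if (side == "pre") {
        sel <- track$t >= enc$t_start - window_h * 3600 & track$t < enc$t_start
        ref <- enc$t_start
      } else {
        sel <- track$t > enc$t_end & track$t <= enc$t_end + window_h * 3600
        ref <- enc$t_end
      }
      w <- track[sel, , drop = FALSE]
      if (nrow(w) < 2L) next
      gap <- hours_between(w$t[-nrow(w)], w$t[-1L])
      okg <- abs(gap - 1) <= tolerance_min / 60
      if (!any(okg)) next
      i2 <- which(okg) + 1L
      out[[length(out) + 1L]] <- data.frame(
        coyote_id = enc$coyote_id, encounter_id = eid,
        time_to_encounter = round(hours_between(ref, w$t[i2])),
        hour_of_day = as.numeric(format(w$t[i2], "%H", tz = "UTC")) +
          as.numeric(format(w$t[i2], "%M", tz = "UTC")) / 60,
        rate = euclid(w$x[i2 - 1L], w$y[i2 - 1L], w$x[i2], w$y[i2]) / gap[i2 - 1L],
        t = w$t[i2])
    }
  }
  if (length(out) == 0L)
    return(data.frame(coyote_id = character(0), encounter_id = character(0),
                      time_to_encounter = numeric(0), hour_of_day = numeric(0),
                      rate = numeric(0), t = as.POSIXct(character(0), tz = "UTC")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the pre/post-encounter movement-rate model
#'
#' Gamma (log link) penalized regression of hourly movement rate on a
#' smooth of time-to-encounter, a cyclic (24-h) smooth of hour of day, and
#' nested random intercepts for coyote and encounter. Non-positive rates
#' are floored at 1 m/h (gamma support) and the flooring is counted.
#'
#' @param rate_records record table from [extract_windows()].
#' @param k_tte,k_hour basis dimensions.
#' @param method smoothing-parameter criterion (default `"GCV.Cp"`).
#' @return a [pgam_fit][fit_pgam].
#' @export
fit_rate_model <- function(rate_records, k_tte = 6, k_hour = 6,
                           method = "GCV.Cp") {
  if (length(unique(rate_records$time_to_encounter)) < 5L)
    stop("need at least 5 distinct time-to-encounter values")
  n_floor <- sum(rate_records$rate <= 0)
  rate_records$rate <- pmax(rate_records$rate, 1)
  fit <- fit_pgam(
    data = rate_records, response = "rate",
    smooths = list(
      list(var = "time_to_encounter", bs = "tp", k = k_tte),
      list(var = "hour_of_day", bs = "cc", k = k_hour)),
    random = c("coyote_id", "encounter_id"),
    family = "gamma", method = method,
    knots = list(hour_of_day = c(0, 24)))
  fit$n_rate_floored <- n_floor
  fit
}

#' Build and fit the encounter step-selection model
#'
#' Observed steps in the 10 h pre- and post-encounter windows are paired
#' with available steps whose lengths come from group-specific gamma fits
#' (pre: shape 0.38, scale 1177.75; post: shape 0.41, scale 1413.39),
#' preserving the observed pre/post difference in movement. Covariates:
#' cos(turn angle), shrub and tree cover proportions in a 256-m-diameter
#' buffer at the step end, TRI at the step end, and distance (m) to the
#' most recent lion fix at the step end; each (except the movement terms)
#' also enters interacted with signed time-to-encounter. Covariates are
#' standardized and the model is fit by conditional logistic regression
#' clustered by coyote.
#'
#' @param coyote_tracks named list of coyote fix data frames.
#' @param lion_tracks named list (or one data frame) of lion fixes.
#' @param encounters independent encounter table.
#' @param landscape landscape with `cover` and `tri` layers.
#' @param seed RNG seed for available-step sampling.
#' @param window_h window, hours (default 10).
#' @param n_available available steps per stratum.
#' @param pre_gamma,post_gamma `c(shape, scale)` for the two groups.
#' @return list with `fit` (clogit_fit), `design`, `scaling`.
#' @export
build_encounter_issf <- function(coyote_tracks, lion_tracks, encounters,
                                 landscape, seed = 1, window_h = 10,
                                 n_available = 10,
                                 pre_gamma = c(0.38, 1177.75),
                                 post_gamma = c(0.41, 1413.39)) {
  if (is.data.frame(lion_tracks)) lion_tracks <- list(lion_tracks)
  lions <- do.call(rbind, lapply(lion_tracks, function(l)
    l[, c("animal_id", "t", "x", "y")]))
  lions <- lions[order(lions$t), , drop = FALSE]

  steps_all <- list()
  for (e in seq_len(nrow(encounters))) {
    enc <- encounters[e, ]
    tr <- coyote_tracks[[enc$coyote_id]]
    if (is.null(tr)) next
    for (side in c("pre", "post")) {
      if (side == "pre") {
        w <- tr[tr$t >= enc$t_start - window_h * 3600 & tr$t < enc$t_start, ]
        ref <- enc$t_start
      } else {
        w <- tr[tr$t > enc$t_end & tr$t <= enc$t_end + window_h * 3600, ]
        ref <- enc$t_end
      }
      if (nrow(w) < 3L) next
      obs <- suppressWarnings(build_steps(w))
      if (nrow(obs) == 0L) next
      obs$stratum <- sprintf("%s_e%d_%s_%s", enc$coyote_id, e, side, obs$stratum)
      obs$group <- side
      obs$time_to_encounter <- round(hours_between(ref, obs$t2))
      steps_all[[length(steps_all) + 1L]] <- obs
    }
  }
  if (length(steps_all) == 0L) stop("no usable steps in encounter windows")
  obs <- do.call(rbind, steps_all)

  design <- do.call(rbind, lapply(c("pre", "post"), function(g) {
    o <- obs[obs$group == g, , drop = FALSE]
    if (nrow(o) == 0L) return(NULL)
    gp <- if (g == "pre") pre_gamma else post_gamma
    d <- sample_available(o[, setdiff(names(o), c("group", "time_to_encounter"))],
                          n = n_available, gamma_shape = gp[1L],
                          gamma_scale = gp[2L],
                          seed = seed + (g == "post"), landscape = landscape)
    d$group <- g
    d$time_to_encounter <- o$time_to_encounter[match(d$stratum, o$stratum)]
    d
  }))

  # covariates at step endpoints
  cp <- cover_proportions(landscape, design$x2, design$y2)
  design$Shrub <- cp[, "shrub"]; design$Tree <- cp[, "tree"]
  design$TRI <- extract_layer(landscape, "tri", design$x2, design$y2)
  design$cosTurnAngle <- cos(design$turn)
  design$StepLength <- design$length
  design$lnStepLength <- log(pmax(design$length, 0.1))
  design$Time2Enc <- design$time_to_encounter
  # distance to the most recent lion fix at the end of the step
  lt <- as.numeric(lions$t)
  idx <- findInterval(as.numeric(design$t2), lt)
  design$DistLion <- ifelse(idx == 0L, NA_real_,
                            euclid(design$x2, design$y2,
                                   lions$x[pmax(idx, 1L)], lions$y[pmax(idx, 1L)]))
  keep_strata <- names(which(tapply(stats::complete.cases(
    design[, c("Shrub", "Tree", "TRI", "DistLion", "cosTurnAngle")]),
    design$stratum, all)))
  design <- design[design$stratum %in% keep_strata, , drop = FALSE]

  main <- c("cosTurnAngle", "Shrub", "Tree", "DistLion", "TRI")
  std <- standardize(design, c("StepLength", "lnStepLength", main, "Time2Enc"))
  design_s <- std$data
  for (v in main) design_s[[paste0(v, ":Time2Enc")]] <- design_s[[v]] * design_s$Time2Enc
  terms <- c("StepLength", "lnStepLength", main, paste0(main, ":Time2Enc"))
  X <- as.matrix(design_s[, terms])
  fit <- fit_clogit(X, design_s$case, design_s$stratum, design_s$animal_id)
  list(fit = fit, design = design_s, scaling = std$scaling, terms = terms)
}
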