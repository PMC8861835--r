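#' Simulate a complete synthetic study scenario
#'
#' Generates a landscape (with terrain layers), biased coyote tracks,
#' mountain-lion tracks with kill-site residencies, and applies GPS fix
#' failure — the study conditions every downstream analysis runs on. The
#' default selection truth gives the coyote an avoidance of the indirect
#' mountain-lion surface (-0.5), an attraction to the indirect kill-site
#' surface (+0.3), mild habitat effects, and no response to the direct
#' metrics; all parameters and seeds are recorded in `truth`.
#'
#' @param seed master seed; all component seeds derive from it.
#' @param n_coyotes,n_lions numbers of animals.
#' @param n_steps hourly coyote steps per animal.
#' @param n_days lion monitoring days (default sized to the coyote span).
#' @param extent landscape cells per axis.
#' @param selection_betas named selection truth on standardized layers.
#' @param gamma_shape,gamma_scale coyote step-length gamma.
#' @param fix_success fix retention probability.
#' @param kill_rate_per_day,residency_mean_days lion kill process.
#' @param lion_interval_h lion fix interval.
#' @param lion_leadin_days days of lion monitoring before the coyote
#'   season starts, so early-season coyote fixes have past risk/reward
#'   sources (default 30). A lion whose draw yields no kills has its seed
#'   redrawn deterministically so the reward analyses are always defined.
#' @return list of class `mesorisk_scenario`: `landscape`, `coyotes`
#'   (named list of fix tables), `lions` (named list), `kills`, `truth`.
#' @export
simulate_scenario <- function(seed = 1, n_coyotes = 3, n_lions = 2,
                              n_steps = 1000, n_days = NULL, extent = 192,
                              selection_betas = c(indirect_lion = -0.5,
                                                  indirect_kill = 0.3,
                                                  shrub_height = 0.2,
                                                  bare_ground = -0.2),
                              gamma_shape = 0.38, gamma_scale = 1402.57,
                              fix_success = 0.898,
                              kill_rate_per_day = 1 / 7,
                              residency_mean_days = 4.5,
                              lion_interval_h = 3, lion_leadin_days = 30) {
  seed <- as.integer(seed)
  land <- gen_landscape(seed, extent = extent)
  land <- add_terrain_layers(land)
  span_days <- ceiling(n_steps / 24) + 2
  if (is.null(n_days)) n_days <- span_days + lion_leadin_days
  size <- extent * land$resolution

  coyotes <- list()
  for (i in seq_len(n_coyotes)) {
    id <- sprintf("C%d", i)
    # starts derive from the seed stream, not the global RNG
    rs <- local_rng(seed * 1000L + i)
    start <- c(size * (0.3 + 0.4 * rs$unif(1)), size * (0.3 + 0.4 * rs$unif(1)))
    tr <- sim_coyote_track(land, start, n_steps,
                           gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                           selection_betas = selection_betas,
                           seed = seed * 100L + i, animal_id = id)
    coyotes[[id]] <- apply_fix_failure(tr, fix_success, seed = seed * 100L + 50L + i)
  }

  lions <- list(); kills <- list()
  lion_t0 <- season_start() - lion_leadin_days * 86400
  for (j in seq_len(n_lions)) {
    id <- sprintf("L%d", j)
    lion_seed <- seed * 100L + 70L + j
    for (try in seq_len(10L)) {
      sim <- sim_lion_track_and_kills(land, n_days,
                                      kill_rate_per_day = kill_rate_per_day,
                                      residency_mean_days = residency_mean_days,
                                      interval_h = lion_interval_h,
                                      seed = lion_seed, animal_id = id,
                                      t0 = lion_t0)
      if (nrow(sim$kills) > 0L || kill_rate_per_day == 0) break
      lion_seed <- lion_seed + 9973L
    }
    lions[[id]] <- sim$track
    kills[[id]] <- sim$kills
  }
  kills <- do.call(rbind, kills)
  rownames(kills) <- NULL

  structure(list(
    landscape = land, coyotes = coyotes, lions = lions, kills = kills,
    truth = list(seed = seed, selection_betas = selection_betas,
                 gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 fix_success = fix_success,
                 kill_rate_per_day = kill_rate_per_day,
                 residency_mean_days = residency_mean_days,
                 n_coyotes = n_coyotes, n_lions = n_lions,
                 n_steps = n_steps, extent = extent)),
    class = "mesorisk_scenario")
}

#' Attach the risk-reward iSSF covariates to a step design
#'
#' Extracts the habitat covariates at step endpoints, the indirect lion
#' and kill occurrence values, and computes the direct metrics (natural
#' log of the minimum distance-by-time-since product) from the lion fixes
#' and kill records. Strata containing a step with any missing covariate
#' (off-landscape endpoint, or no past source for a direct metric) are
#' dropped whole and counted.
#'
#' @param design step data frame from [sample_available()].
#' @param landscape landscape with terrain and indirect layers.
#' @param lion_fixes pooled lion fix data frame (direct risk sources).
#' @param kills kill table (direct reward sources; event time is the
#'   kill's first lion fix).
#' @return list with `design` (complete strata only, covariates attached)
#'   and `n_strata_dropped`.
#' @export
attach_issf_covariates <- function(design, landscape, lion_fixes, kills) {
  lay <- function(nm) extract_layer(landscape, nm, design$x2, design$y2)
  design$StepLength <- design$length
  design$lnStepLength <- log(pmax(design$length, 0.1))
  design$DistRoads <- lay("dist_road")
  design$DistAspen <- lay("dist_aspen")
  design$DistFor <- lay("dist_forest")
  design$Elev <- lay("elev")
  design$TPI <- lay("tpi")
  design$TRI <- lay("tri")
  design$ShrubHeight <- lay("shrub_height")
  design$BareGround <- lay("bare_ground")
  design$Herb <- lay("herb")
  design$SageHeight <- lay("sage_height")
  design$IndirectLion <- lay("indirect_lion")
  design$IndirectKill <- lay("indirect_kill")

  q <- data.frame(t = design$t2, x = design$x2, y = design$y2)
  dm_lion <- direct_metric(q, lion_fixes[, c("t", "x", "y")])
  design$lnDirectLion <- dm_lion$ln_value
  ksrc <- data.frame(t = kills$t_first, x = kills$x, y = kills$y)
  dm_kill <- direct_metric(q, ksrc)
  design$lnDirectKill <- dm_kill$ln_value

  need <- c("DistRoads", "DistAspen", "DistFor", "Elev", "TPI", "TRI",
            "ShrubHeight", "BareGround", "Herb", "SageHeight",
            "IndirectLion", "IndirectKill", "lnDirectLion", "lnDirectKill")
  ok <- stats::complete.cases(design[, need])
  keep <- names(which(tapply(ok, design$stratum, all)))
  n_drop <- length(unique(design$stratum)) - length(keep)
  design <- design[design$stratum %in% keep, , drop = FALSE]
  list(design = design, n_strata_dropped = n_drop)
}

#' Run the direct-versus-indirect iSSF model comparison
#'
#' Builds observed/available step designs from the scenario's coyote
#' tracks, attaches covariates, VIF-prunes the habitat set, standardizes,
#' fits the five candidate models by conditional logistic regression
#' clustered by coyote, and ranks them by QIC.
#'
#' @param scenario a [simulate_scenario()] result (or compatible list).
#' @param seed RNG seed for available-step sampling.
#' @param n_available available steps per stratum.
#' @param vif_threshold multicollinearity threshold.
#' @param out_dir optional directory to write `ranking.csv`,
#'   `best_model.csv`, `vif_removals.txt` and `manifest.txt`.
#' @return list: `ranking`, `fits`, `best` (name), `coef_table`
#'   (Table-2-style summary of the best model), `scaling`, `vif`,
#'   `n_strata`, `n_strata_dropped`.
#' @export
run_issf_comparison <- function(scenario, seed = 1, n_available = 10,
                                vif_threshold = 3, out_dir = NULL) {
  land <- scenario$landscape
  obs <- do.call(rbind, lapply(scenario$coyotes, function(tr)
    suppressWarnings(build_steps(tr))))
  if (nrow(obs) == 0L) stop("no strata could be formed from the coyote tracks")
  design <- sample_available(obs, n = n_available,
                             gamma_shape = scenario$truth$gamma_shape,
                             gamma_scale = scenario$truth$gamma_scale,
                             seed = seed, landscape = land)
  lion_fixes <- do.call(rbind, lapply(scenario$lions, function(l)
    l[, c("animal_id", "t", "x", "y")]))
  att <- attach_issf_covariates(design, land, lion_fixes, scenario$kills)
  design <- att$design

  habitat <- c("DistRoads", "DistAspen", "DistFor", "Elev", "TPI", "TRI",
               "ShrubHeight", "BareGround", "Herb", "SageHeight")
  vp <- vif_prune(design[design$case == 0L, habitat], threshold = vif_threshold)
  retained_habitat <- vp$retained

  metric_cols <- c("IndirectLion", "IndirectKill", "lnDirectLion", "lnDirectKill")
  model_cols <- c("StepLength", "lnStepLength", retained_habitat, metric_cols)
  std <- standardize(design, model_cols)
  dstd <- std$data

  specs <- build_model_set(design)
  specs <- lapply(specs, function(sp)
    intersect(sp, c("StepLength", "lnStepLength", retained_habitat, metric_cols)))
  fits <- lapply(specs, function(sp)
    fit_clogit(as.matrix(dstd[, sp]), dstd$case, dstd$stratum, dstd$animal_id))
  ranking <- rank_models(fits)
  best <- ranking$model[1L]
  bf <- fits[[best]]
  coef_table <- data.frame(predictor = names(bf$coef), beta = unname(bf$coef),
                           se = unname(bf$se), z = unname(bf$z),
                           p = unname(bf$p))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(ranking, file.path(out_dir, "ranking.csv"), row.names = FALSE)
    utils::write.csv(coef_table, file.path(out_dir, "best_model.csv"), row.names = FALSE)
    writeLines(c("column vif step",
                 sprintf("%s %.3f %d", vp$removed$column, vp$removed$vif,
                         vp$removed$step)),
               file.path(out_dir, "vif_removals.txt"))
    write_manifest(file.path(out_dir, "manifest.txt"), list(
      stage = "issf_comparison", seed = seed,
      n_strata = bf$n_strata, n_strata_dropped = att$n_strata_dropped,
      best_model = best))
  }
  list(ranking = ranking, fits = fits, best = best, coef_table = coef_table,
       scaling = std$scaling, vif = vp, n_strata = bf$n_strata,
       n_strata_dropped = att$n_strata_dropped)
}

#' Run the encounter detection and pre/post-encounter analyses
#'
#' Detects coyote-lion encounters (1 km / 2 h), merges bouts, applies the
#' 5-h independence filter, fits the movement-rate model on the 5-h
#' windows and the encounter step-selection model on the 10-h windows.
#'
#' @param scenario a scenario.
#' @param seed RNG seed for available-step sampling.
#' @param dist_km,dt_h,gap_h,rate_window_h,issf_window_h thresholds.
#' @param out_dir optional output directory.
#' @return list: `encounters`, `rate_records`, `rate_fit`,
#'   `rate_curve` (Fig-4-style prediction grid), `issf` (fit + design; NULL
#'   when too few encounters), `counts` (raw pairs, bouts, independent,
#'   multi-hour fraction).
#' @export
run_encounter_analysis <- function(scenario, seed = 1, dist_km = 1, dt_h = 2,
                                   gap_h = 5, rate_window_h = 5,
                                   issf_window_h = 10, out_dir = NULL) {
  pairs_all <- list(); bouts_all <- list()
  for (cid in names(scenario$coyotes)) for (lid in names(scenario$lions)) {
    p <- detect_encounters(scenario$coyotes[[cid]], scenario$lions[[lid]],
                           dist_km = dist_km, dt_h = dt_h)
    if (nrow(p)) {
      pairs_all[[paste(cid, lid)]] <- p
      bouts_all[[paste(cid, lid)]] <- merge_bouts(p)
    }
  }
  n_pairs <- sum(vapply(pairs_all, nrow, 0L))
  bouts <- if (length(bouts_all)) do.call(rbind, bouts_all) else
    merge_bouts(detect_encounters(scenario$coyotes[[1L]][0L, ], scenario$lions[[1L]]))
  rownames(bouts) <- NULL
  enc <- filter_independent(bouts, gap_h = gap_h)
  counts <- list(n_raw_pairs = n_pairs, n_bouts = nrow(bouts),
                 n_independent = nrow(enc),
                 multi_hour_fraction = if (nrow(enc)) mean(enc$multi_hour) else NA_real_)
  if (nrow(enc) == 0L) {
    message("no independent encounters detected")
    return(list(encounters = enc, rate_records = NULL, rate_fit = NULL,
                rate_curve = NULL, issf = NULL, counts = counts))
  }

  rr <- do.call(rbind, lapply(names(scenario$coyotes), function(cid)
    extract_windows(scenario$coyotes[[cid]],
                    enc[enc$coyote_id == cid, , drop = FALSE],
                    window_h = rate_window_h)))
  rate_fit <- NULL; rate_curve <- NULL
  if (!is.null(rr) && nrow(rr) > 20L &&
      length(unique(rr$time_to_encounter)) >= 5L) {
    rate_fit <- fit_rate_model(rr)
    grid <- data.frame(
      time_to_encounter = seq(min(rr$time_to_encounter),
                              max(rr$time_to_encounter), by = 0.25),
      hour_of_day = stats::median(rr$hour_of_day))
    rate_curve <- predict_with_ci(rate_fit, grid)
  }

  issf <- tryCatch(
    build_encounter_issf(scenario$coyotes, scenario$lions, enc,
                         scenario$landscape, seed = seed,
                         window_h = issf_window_h),
    error = function(e) { message("encounter iSSF skipped: ", conditionMessage(e)); NULL })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ec <- enc
    ec$t_start <- format(ec$t_start, "%Y-%m-%dT%H:%M:%SZ")
    ec$t_end <- format(ec$t_end, "%Y-%m-%dT%H:%M:%SZ")
    utils::write.csv(ec, file.path(out_dir, "encounters.csv"), row.names = FALSE)
    if (!is.null(rr)) utils::write.csv(rr, file.path(out_dir, "rate_records.csv"),
                                       row.names = FALSE)
    if (!is.null(rate_curve)) utils::write.csv(rate_curve,
      file.path(out_dir, "rate_curve.csv"), row.names = FALSE)
    if (!is.null(issf)) {
      ct <- data.frame(predictor = names(issf$fit$coef),
                       beta = unname(issf$fit$coef), se = unname(issf$fit$se),
                       z = unname(issf$fit$z), p = unname(issf$fit$p))
      utils::write.csv(ct, file.path(out_dir, "encounter_issf.csv"), row.names = FALSE)
    }
    write_manifest(file.path(out_dir, "manifest.txt"), c(
      list(stage = "encounter_analysis", seed = seed), counts))
  }
  list(encounters = enc, rate_records = rr, rate_fit = rate_fit,
       rate_curve = rate_curve, issf = issf, counts = counts)
}

#' Run the kill-site concentric-ring use analysis
#'
#' Screens kills for coyote accessibility, builds ring-day use records for
#' the 14 days before and after each kill, fits the pre- and post-kill
#' binomial models, and produces Fig-6-style prediction curves (day curve
#' at the innermost ring, distance curve at the post-kill peak day;
#' offsets at the innermost ring area and unit fix rate; local count at
#' its median).
#'
#' @param scenario a scenario.
#' @param out_dir optional output directory.
#' @return list: `kills` (with eligibility flags), `records_pre`,
#'   `records_post`, `fit_pre`, `fit_post`, `curves` (list of prediction
#'   grids), `counts`.
#' @export
run_killsite_analysis <- function(scenario, out_dir = NULL) {
  fixes <- do.call(rbind, lapply(scenario$coyotes, function(x)
    x[, c("animal_id", "t", "x", "y")]))
  kills <- eligibility_filter(scenario$kills, fixes)
  counts <- list(n_kills = nrow(kills),
                 n_pre_eligible = sum(kills$pre_eligible),
                 n_post_eligible = sum(kills$post_eligible))
  if (sum(kills$post_eligible) == 0L && sum(kills$pre_eligible) == 0L) {
    message("no eligible kills")
    return(list(kills = kills, counts = counts))
  }
  res <- list(kills = kills, counts = counts)
  for (side in c("pre", "post")) {
    n_el <- if (side == "pre") sum(kills$pre_eligible) else sum(kills$post_eligible)
    if (n_el < 5L) { message("fewer than 5 eligible kills for the ", side, " window"); next }
    rec <- build_ring_records(kills, fixes, side = side)
    res[[paste0("records_", side)]] <- rec
    res[[paste0("fit_", side)]] <- fit_killsite_model(rec, side = side)
  }
  curves <- list()
  for (side in c("pre", "post")) {
    fk <- res[[paste0("fit_", side)]]
    rec <- res[[paste0("records_", side)]]
    if (is.null(fk)) next
    ref <- data.frame(ring_area = ring_areas()[1L], inv_fix_rate = 1,
                      local_count = stats::median(rec$local_count),
                      lion_active_n = 0L)
    day_grid <- cbind(data.frame(day_abs = seq(1, 14, by = 0.25), dist_m = 50), ref)
    curves[[paste0(side, "_day")]] <- predict_with_ci(fk$fit, day_grid)
    peak_day <- if (side == "post")
      day_grid$day_abs[which.max(curves$post_day$fit)] else 7
    dist_grid <- cbind(data.frame(day_abs = peak_day,
                                  dist_m = seq(50, 950, by = 25)), ref)
    curves[[paste0(side, "_dist")]] <- predict_with_ci(fk$fit, dist_grid)
  }
  res$curves <- curves

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (side in c("pre", "post")) {
      rec <- res[[paste0("records_", side)]]
      if (!is.null(rec))
        utils::write.csv(rec, file.path(out_dir, sprintf("ring_records_%s.csv", side)),
                         row.names = FALSE)
    }
    for (nm in names(curves))
      utils::write.csv(curves[[nm]], file.path(out_dir, sprintf("curve_%s.csv", nm)),
                       row.names = FALSE)
    write_manifest(file.path(out_dir, "manifest.txt"),
                   c(list(stage = "killsite_analysis"), counts))
  }
  res
}

# flat key = value run manifest
write_manifest <- function(path, values) {
  writeLines(sprintf("%s = %s", names(values),
                     vapply(values, function(v) paste(format(v), collapse = ","), "")),
             path)
  invisible(path)
}
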