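test_that("pair detection applies both thresholds inclusively", {
  t0 <- season_start_test()
  ct <- make_fixes(cbind(0, 0))
  ct$t <- t0 + 10 * 3600
  lt <- make_fixes(cbind(0, 900), id = "L1", species = "lion")
  lt$t <- t0 + 11.5 * 3600
  p <- detect_encounters(ct, lt)
  expect_identical(nrow(p), 1L)
  expect_equal(p$dist_m, 900)

  lt$t <- t0 + 35 * 3600   # 11:00 the next day
  expect_identical(nrow(detect_encounters(ct, lt)), 0L)

  # parallel tracks 5 km apart never pair
  ct2 <- make_fixes(cbind(seq(0, 5000, by = 500), 0))
  lt2 <- make_fixes(cbind(seq(0, 5000, by = 500), 5000), id = "L1",
                    species = "lion")
  expect_identical(nrow(detect_encounters(ct2, lt2)), 0L)
  expect_identical(nrow(detect_encounters(ct2[0, ], lt2)), 0L)
})

test_that("detection equals the brute-force double loop on random tracks", {
  set.seed(13)
  t0 <- season_start_test()
  for (rep in 1:25) {
    nc <- sample(5:25, 1); nl <- sample(5:25, 1)
    ct <- data.frame(animal_id = "C1", species = "coyote",
                     t = t0 + sort(runif(nc, 0, 48)) * 3600,
                     x = runif(nc, 0, 4000), y = runif(nc, 0, 4000))
    lt <- data.frame(animal_id = "L1", species = "lion",
                     t = t0 + sort(runif(nl, 0, 48)) * 3600,
                     x = runif(nl, 0, 4000), y = runif(nl, 0, 4000))
    got <- detect_encounters(ct, lt)
    want <- brute_pairs(ct, lt)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      got_k <- sort(paste(got$t_coyote, got$t_lion))
      want_k <- sort(paste(ct$t[want[, 1]], lt$t[want[, 2]]))
      expect_identical(got_k, want_k)
    }
  }
})

test_that("bout merging and the independence filter follow the stated rules", {
  t0 <- season_start_test()
  mkpairs <- function(hours) data.frame(
    coyote_id = "C1", lion_id = "L1",
    t_coyote = t0 + hours * 3600, t_lion = t0 + hours * 3600,
    dist_m = 500, dt_h = 0)

  b <- merge_bouts(mkpairs(c(10, 11, 12)))
  expect_identical(nrow(b), 1L)
  expect_equal(b$t_start, t0 + 10 * 3600)
  expect_equal(b$t_end, t0 + 12 * 3600)
  expect_true(b$multi_hour)

  b1 <- merge_bouts(mkpairs(10))
  expect_identical(b1$t_start, b1$t_end)
  expect_false(b1$multi_hour)

  b2 <- merge_bouts(mkpairs(c(10, 14)))
  expect_identical(nrow(b2), 2L)

  # 3-h separation < 5-h gap: second dropped; exactly 5 h: retained
  enc <- rbind(
    data.frame(coyote_id = "C1", lion_id = "L1", t_start = t0 + 10 * 3600,
               t_end = t0 + 12 * 3600, n_pairs = 3L, multi_hour = TRUE),
    data.frame(coyote_id = "C1", lion_id = "L1", t_start = t0 + 15 * 3600,
               t_end = t0 + 15 * 3600, n_pairs = 1L, multi_hour = FALSE),
    data.frame(coyote_id = "C1", lion_id = "L1", t_start = t0 + 17 * 3600,
               t_end = t0 + 17 * 3600, n_pairs = 1L, multi_hour = FALSE))
  kept <- filter_independent(enc)
  expect_identical(nrow(kept), 2L)
  expect_equal(kept$t_start, c(t0 + 10 * 3600, t0 + 17 * 3600))

  one <- filter_independent(enc[1, ])
  expect_identical(nrow(one), 1L)
  # idempotence of the merged/filtered pipeline
  expect_identical(nrow(filter_independent(kept)), nrow(kept))
})

test_that("window extraction computes signed hourly rates outside the bout", {
  t0 <- season_start_test()
  xy <- cbind(cumsum(c(0, rep(500, 14))), 0)
  tr <- make_fixes(xy)
  enc <- data.frame(coyote_id = "C1", lion_id = "L1",
                    t_start = t0 + 6 * 3600, t_end = t0 + 8 * 3600,
                    n_pairs = 3L, multi_hour = TRUE)
  rr <- extract_windows(tr, enc, window_h = 5)
  expect_true(all(rr$rate == 500))
  expect_true(all(rr$time_to_encounter != 0))
  expect_true(all(rr$time_to_encounter >= -5 & rr$time_to_encounter <= 5))
  # fixes inside [t_start, t_end] are excluded
  in_bout <- tr$t[tr$t >= enc$t_start & tr$t <= enc$t_end]
  expect_false(any(rr$t %in% in_bout))
  # a fix 3 h before the start carries time_to_encounter -3
  expect_true(any(rr$time_to_encounter == -3))
  expect_equal(rr$rate[rr$time_to_encounter == -3], 500)
})

test_that("the movement-rate model recovers a peak at the encounter", {
  set.seed(14)
  tte <- rep(c(-5:-1, 1:5), each = 60)
  mu <- 400 + 700 * exp(-tte^2 / 4)
  rr <- data.frame(coyote_id = rep(c("C1", "C2"), 300),
                   encounter_id = rep(sprintf("e%d", 1:12), each = 50),
                   time_to_encounter = tte,
                   hour_of_day = sample(0:23, 600, TRUE),
                   rate = rgamma(600, shape = 4, scale = mu / 4))
  fit <- fit_rate_model(rr)
  grid <- data.frame(time_to_encounter = seq(-5, 5, by = 0.1),
                     hour_of_day = 12)
  pred <- predict_with_ci(fit, grid)
  peak <- grid$time_to_encounter[which.max(pred$fit)]
  expect_lte(abs(peak), 1 + 0.1)

  # constant rates shrink the smooth towards a flat line
  rr2 <- rr; rr2$rate <- rgamma(600, shape = 50, scale = 10)
  fit2 <- fit_rate_model(rr2)
  expect_lt(unname(fit2$edf["s(time_to_encounter)"]), 1.6)
  expect_error(fit_rate_model(rr[rr$time_to_encounter %in% c(-1, 1), ]),
               "5 distinct")
})

test_that("encounter iSSF uses group gammas and returns Table-3-style terms", {
  obs <- data.frame(stratum = paste0("s", 1:2000), animal_id = "C1",
                    t1 = season_start_test(), t2 = season_start_test() + 3600,
                    x1 = 0, y1 = 0, x2 = 100, y2 = 0,
                    length = 100, bearing = 0, prev_bearing = 0, turn = 0)
  pre <- sample_available(obs, n = 5, gamma_shape = 0.38, gamma_scale = 1177.75,
                          seed = 5)
  m_pre <- mean(pre$length[pre$case == 0L])
  expect_lt(abs(m_pre - 0.38 * 1177.75) / (0.38 * 1177.75), 0.05)
  post <- sample_available(obs, n = 5, gamma_shape = 0.41, gamma_scale = 1413.39,
                           seed = 6)
  m_post <- mean(post$length[post$case == 0L])
  expect_lt(abs(m_post - 0.41 * 1413.39) / (0.41 * 1413.39), 0.05)

  sc <- simulate_scenario(seed = 21, n_coyotes = 2, n_lions = 1,
                          n_steps = 400, extent = 96,
                          selection_betas = numeric(0), fix_success = 1)
  ea <- run_encounter_analysis(sc, seed = 21)
  expect_gt(ea$counts$n_independent, 0)
  expect_false(is.null(ea$issf))
  nm <- names(ea$issf$fit$coef)
  expect_true(all(c("cosTurnAngle", "Shrub", "Tree", "DistLion", "TRI",
                    "DistLion:Time2Enc") %in% nm))
  expect_identical(ea$issf$fit$K, 12L)
})

test_that("coyotes that ignore lions show a null distance-by-time interaction", {
  covered <- 0L
  for (s in 1:5) {
    sc <- simulate_scenario(seed = 30 + s, n_coyotes = 2, n_lions = 1,
                            n_steps = 400, extent = 96,
                            selection_betas = numeric(0), fix_success = 1)
    ea <- run_encounter_analysis(sc, seed = 30 + s)
    if (is.null(ea$issf)) next
    f <- ea$issf$fit
    b <- f$coef["DistLion:Time2Enc"]
    se <- f$se_naive["DistLion:Time2Enc"]
    if (abs(b) < 1.96 * se) covered <- covered + 1L
  }
  expect_gte(covered, 4L)
})
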