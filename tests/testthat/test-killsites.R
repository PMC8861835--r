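ks_kill <- function(x = 0, y = 0, t0 = season_start_test() + 20 * 86400,
                    resid_days = 4.5, id = "K1") {
  data.frame(id = id, x = x, y = y, t_first = t0,
             t_last = t0 + resid_days * 86400, prey_large = TRUE)
}

test_that("ring areas tile the 1000-m disc exactly", {
  a <- ring_areas()
  expect_identical(length(a), 10L)
  expect_equal(sum(a), pi * 1000^2)
  expect_equal(a[1], pi * 100^2)
})

test_that("eligibility uses the 1000-m/14-day rule with inclusive boundary", {
  k <- ks_kill()
  t0 <- k$t_first
  far <- data.frame(animal_id = "C1", t = t0, x = 5000, y = 0)
  kk <- eligibility_filter(k, far)
  expect_false(kk$pre_eligible); expect_false(kk$post_eligible)

  post_only <- data.frame(animal_id = "C1", t = t0 + 3 * 86400, x = 500, y = 0)
  kk <- eligibility_filter(k, post_only)
  expect_false(kk$pre_eligible); expect_true(kk$post_eligible)

  boundary <- data.frame(animal_id = "C1", t = t0 - 2 * 86400, x = 1000, y = 0)
  kk <- eligibility_filter(k, boundary)
  expect_true(kk$pre_eligible)
})

test_that("ring-day classification follows the boundary conventions", {
  k <- ks_kill()
  t0 <- k$t_first
  f1 <- data.frame(animal_id = "C1", t = t0 + 1.5 * 86400, x = 50, y = 0)
  rec <- classify_use(k, f1, side = "post")
  expect_identical(nrow(rec), 140L)
  expect_true(rec$used[rec$ring == 1 & rec$day == 2])
  expect_identical(sum(rec$used), 1L)

  # upper-inclusive annuli: exactly 100 m falls in ring 1
  f2 <- data.frame(animal_id = "C1", t = t0 + 0.5 * 86400, x = 100, y = 0)
  rec2 <- classify_use(k, f2, side = "post")
  expect_true(rec2$used[rec2$ring == 1 & rec2$day == 1])
  f3 <- data.frame(animal_id = "C1", t = t0 + 0.5 * 86400, x = 100.001, y = 0)
  rec3 <- classify_use(k, f3, side = "post")
  expect_true(rec3$used[rec3$ring == 2 & rec3$day == 1])

  none <- classify_use(k, far <- data.frame(animal_id = "C1", t = t0 + 86400,
                                            x = 99999, y = 0), side = "post")
  expect_identical(sum(none$used), 0L)
  expect_identical(nrow(none), 140L)

  pre <- classify_use(k, data.frame(animal_id = "C1", t = t0 - 0.5 * 86400,
                                    x = 250, y = 0), side = "pre")
  expect_true(pre$used[pre$ring == 3 & pre$day == -1])
})

test_that("classification equals a brute-force per-fix loop on random fixtures", {
  set.seed(20)
  k <- ks_kill()
  t0 <- k$t_first
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    fx <- data.frame(animal_id = "C1",
                     t = t0 + runif(n, -16, 16) * 86400,
                     x = runif(n, -1500, 1500), y = runif(n, -1500, 1500))
    rec <- classify_use(k, fx, side = "post")
    for (r in sample(10, 3)) for (d in sample(14, 3)) {
      inside <- vapply(seq_len(n), function(i) {
        dist <- sqrt(fx$x[i]^2 + fx$y[i]^2)
        dd <- as.numeric(difftime(fx$t[i], t0, units = "days"))
        dist > (r - 1) * 100 && dist <= r * 100 && dd >= (d - 1) && dd < d
      }, TRUE)
      expect_identical(rec$used[rec$ring == r & rec$day == d], any(inside))
    }
  }
})

test_that("local intensity divides counts by the fix rate within the radius", {
  k <- ks_kill()
  t0 <- k$t_first
  fx <- data.frame(animal_id = "C1", t = t0 + rep(1:10) * 86400 / 20,
                   x = seq(100, 1000, by = 100), y = 0)
  expect_equal(local_intensity(k, fx, fix_rate = 1, side = "post"), 10)
  expect_equal(local_intensity(k, fx[1:9, ], fix_rate = 0.9, side = "post"), 10)
  fx_out <- fx; fx_out$x <- fx_out$x + 5000
  expect_equal(local_intensity(k, fx_out, fix_rate = 1, side = "post"), 0)
  expect_error(local_intensity(k, fx, fix_rate = 0, side = "post"), "positive")
})

test_that("record building yields eligible x 10 x 14 rows with flags", {
  set.seed(21)
  t0 <- season_start_test() + 20 * 86400
  kills <- do.call(rbind, lapply(1:6, function(i)
    ks_kill(x = i * 4000, t0 = t0 + i * 86400, id = paste0("K", i))))
  fx <- do.call(rbind, lapply(1:6, function(i)
    data.frame(animal_id = "C1",
               t = t0 + i * 86400 + runif(30, 0, 13.9) * 86400,
               x = i * 4000 + runif(30, -900, 900), y = runif(30, -900, 900))))
  kk <- eligibility_filter(kills, fx)
  expect_true(all(kk$post_eligible))
  rec <- build_ring_records(kk, fx, side = "post")
  expect_identical(nrow(rec), sum(kk$post_eligible) * 140L)
  # lion occupancy flag follows the 4.5-day residency
  expect_true(all(rec$lion_active[rec$day <= 4]))
  expect_false(any(rec$lion_active[rec$day >= 6]))
  expect_true(all(rec$fix_rate > 0 & rec$fix_rate <= 1))
})

test_that("synthetic close-ring use in days 3-6 is recovered by the post model", {
  set.seed(22)
  t0 <- season_start_test() + 20 * 86400
  n_kill <- 25
  rec <- do.call(rbind, lapply(seq_len(n_kill), function(i) {
    r <- expand.grid(ring = 1:10, day = 1:14)
    p <- ifelse(r$ring == 1 & r$day >= 3 & r$day <= 6, 0.85,
                ifelse(r$ring == 1, 0.25, 0.02))
    data.frame(kill_id = paste0("K", i), ring = r$ring, day = r$day,
               used = runif(140) < p, ring_area = ring_areas()[r$ring],
               dist_m = (r$ring - 0.5) * 100, day_abs = r$day,
               local_count = 30, fix_rate = 1, lion_active = r$day <= 5)
  }))
  fit <- fit_killsite_model(rec, side = "post")
  ref <- data.frame(ring_area = ring_areas()[1], inv_fix_rate = 1,
                    local_count = 30, lion_active_n = 0L)
  day_grid <- cbind(data.frame(day_abs = seq(1, 14, by = 0.25), dist_m = 50), ref)
  day_curve <- predict_with_ci(fit$fit, day_grid)
  peak_day <- day_grid$day_abs[which.max(day_curve$fit)]
  expect_gte(peak_day, 3); expect_lte(peak_day, 6)
  dist_grid <- cbind(data.frame(day_abs = peak_day,
                                dist_m = seq(50, 950, by = 100)), ref)
  dist_curve <- predict_with_ci(fit$fit, dist_grid)
  expect_identical(which.max(dist_curve$fit), 1L)
})

test_that("null scenarios shrink smooths and eliminate the lion flag", {
  set.seed(23)
  # null use: constant intensity per unit area, so the area offset alone
  # explains the ring pattern and both smooths should shrink to flat
  make_null_rec <- function(n_kill) {
    do.call(rbind, lapply(seq_len(n_kill), function(i) {
      r <- expand.grid(ring = 1:10, day = 1:14)
      p <- 0.005 * (2 * r$ring - 1)
      data.frame(kill_id = paste0("K", i), ring = r$ring, day = r$day,
                 used = runif(140) < p, ring_area = ring_areas()[r$ring],
                 dist_m = (r$ring - 0.5) * 100, day_abs = r$day,
                 local_count = 30, fix_rate = 1, lion_active = r$day <= 5)
    }))
  }
  elim <- 0L
  for (s in 1:5) {
    rec <- make_null_rec(15)
    fit <- fit_killsite_model(rec, side = "post")
    if (!"lion_active_n" %in% fit$retained) elim <- elim + 1L
  }
  expect_gte(elim, 4L)

  rec <- make_null_rec(20)
  f <- fit_killsite_model(rec, side = "post")$fit
  expect_lt(unname(f$edf["s(day_abs)"]), 1.8)
  expect_lt(unname(f$edf["s(dist_m)"]), 1.8)
  expect_error(fit_killsite_model(make_null_rec(3), side = "post"), "5 eligible")
})
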