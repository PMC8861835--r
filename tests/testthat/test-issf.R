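test_that("step building honours bursts, turn angles and gaps", {
  xy <- cbind(c(0, 300, 300, 600, 600), c(0, 0, 300, 300, 600))
  fx <- make_fixes(xy)
  st <- build_steps(fx)
  expect_identical(nrow(st), 3L)          # first step lacks a turn angle
  expect_equal(st$length[1], sqrt(0^2 + 300^2))
  expect_equal(st$turn[1], pi / 2)

  # a 2-h gap splits bursts and removes the spanning and following stratum
  fx2 <- fx
  fx2$t[4:5] <- fx2$t[4:5] + 3600
  st2 <- build_steps(fx2)
  expect_identical(nrow(st2), 1L)

  expect_warning(build_steps(fx[1:2, ]), "3 fixes")
  # 300-m displacement gives a 300-m step
  expect_equal(build_steps(make_fixes(cbind(c(0, 300, 600), 0)))$length, 300)
})

test_that("available steps follow the stated sampling distributions", {
  obs <- data.frame(stratum = paste0("s", 1:1000), animal_id = "C1",
                    t1 = season_start_test(), t2 = season_start_test() + 3600,
                    x1 = 0, y1 = 0, x2 = 100, y2 = 0,
                    length = 100, bearing = 0, prev_bearing = 0, turn = 0)
  d <- sample_available(obs, n = 10, seed = 1)
  av <- d[d$case == 0L, ]
  expect_identical(nrow(av), 10000L)
  expect_lt(abs(mean(av$length) - 533) / 533, 0.05)
  ks <- suppressWarnings(ks.test(av$turn, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  expect_equal(formals(sample_available)$n, 10)
  # endpoints placed by the drawn geometry
  expect_equal(av$x2, av$x1 + av$length * cos(av$bearing))
})

test_that("conditional-logistic likelihood and toy fits are exact", {
  # 11 identical steps in one stratum: symmetric multinomial
  X <- matrix(1, 11, 1, dimnames = list(NULL, "c1"))
  f <- suppressWarnings(fit_clogit(X, c(1, rep(0, 10)), rep("s1", 11), rep("a", 11)))
  expect_equal(f$quasi_ll, log(1 / 11))
  expect_equal(unname(f$coef), 0)

  # two-strata toy with one binary covariate: grid-search oracle
  # (mixed outcomes so the maximizer is finite)
  X2 <- matrix(c(1, 0, 1, 0, 1, 0), ncol = 1, dimnames = list(NULL, "b"))
  case2 <- c(1, 0, 0, 1, 0, 0)
  str2 <- rep(c("s1", "s2"), each = 3)
  ll <- function(b) {
    eta <- X2[, 1] * b
    sum(tapply(seq_along(eta), str2, function(ii)
      eta[ii][case2[ii] == 1] - log(sum(exp(eta[ii])))))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, ll, 0))]
  f2 <- fit_clogit(X2, case2, str2, rep("a", 6))
  expect_equal(unname(f2$coef), b_star, tolerance = 1e-4)

  # likelihood at beta = 0 is n_strata * ln(1/11) exactly
  obs <- data.frame(stratum = paste0("s", 1:40), animal_id = "C1",
                    t1 = season_start_test(), t2 = season_start_test() + 3600,
                    x1 = 0, y1 = 0, x2 = 100, y2 = 0,
                    length = 100, bearing = 0, prev_bearing = 0, turn = 0)
  d <- sample_available(obs, seed = 2)
  Xc <- matrix(1, nrow(d), 1, dimnames = list(NULL, "const"))
  f0 <- suppressWarnings(fit_clogit(Xc, d$case, d$stratum, d$animal_id))
  expect_equal(f0$quasi_ll, 40 * log(1 / 11))
})

test_that("fits are invariant to stratum-level shifts and row order", {
  set.seed(9)
  n_str <- 60
  d <- data.frame(stratum = rep(paste0("s", 1:n_str), each = 4),
                  case = rep(c(1, 0, 0, 0), n_str),
                  cluster = rep(rep(c("a", "b"), each = 2), n_str))
  X <- matrix(rnorm(nrow(d) * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  f1 <- fit_clogit(X, d$case, d$stratum, d$cluster)

  # adding a stratum-constant to a covariate changes nothing
  shift <- ave(rnorm(nrow(d)), d$stratum, FUN = function(z) z[1] * 0 + rnorm(1))
  X2 <- X; X2[, 1] <- X2[, 1] + shift
  f2 <- fit_clogit(X2, d$case, d$stratum, d$cluster)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-6)
  expect_equal(f2$quasi_ll, f1$quasi_ll, tolerance = 1e-8)

  # permuting rows within strata changes nothing
  perm <- order(d$stratum, rnorm(nrow(d)))
  f3 <- fit_clogit(X[perm, ], d$case[perm], d$stratum[perm], d$cluster[perm])
  expect_equal(f3$coef, f1$coef, tolerance = 1e-6)

  # global affine rescale of a covariate rescales its beta
  X4 <- X; X4[, 1] <- 2 * X4[, 1] + 7
  f4 <- fit_clogit(X4, d$case, d$stratum, d$cluster)
  expect_equal(unname(f4$coef[1]), unname(f1$coef[1]) / 2, tolerance = 1e-6)
})

test_that("cluster-robust covariance matches survival's sandwich", {
  library(survival)
  set.seed(10)
  n_str <- 80
  d <- data.frame(stratum = rep(seq_len(n_str), each = 5),
                  case = rep(c(1, 0, 0, 0, 0), n_str),
                  cluster = rep(sample(letters[1:8], n_str, TRUE), each = 5))
  X <- matrix(rnorm(nrow(d) * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  ours <- fit_clogit(X, d$case, d$stratum, d$cluster)
  sv <- clogit(case ~ X[, 1] + X[, 2] + strata(stratum) + cluster(cluster),
               data = d, method = "breslow")
  expect_equal(unname(ours$coef), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(sv)))), tolerance = 1e-4)
})

test_that("separation and degenerate designs raise informative errors", {
  d <- data.frame(stratum = rep(c("s1", "s2"), each = 3),
                  case = c(1, 0, 0, 1, 0, 0))
  Xsep <- matrix(d$case, ncol = 1, dimnames = list(NULL, "leak"))
  expect_error(fit_clogit(Xsep, d$case, d$stratum, rep("a", 6)), "leak")
  expect_error(fit_clogit(Xsep, c(1, 1, 0, 1, 0, 0), d$stratum, rep("a", 6)),
               "exactly one")
})

test_that("QIC reduces to -2Q + 2K when robust equals naive", {
  set.seed(11)
  obs <- data.frame(stratum = paste0("s", 1:50), animal_id = "C1",
                    t1 = season_start_test(), t2 = season_start_test() + 3600,
                    x1 = 0, y1 = 0, x2 = 100, y2 = 0,
                    length = 100, bearing = 0, prev_bearing = 0, turn = 0)
  d <- sample_available(obs, seed = 3)
  X <- matrix(rnorm(nrow(d) * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  f <- fit_clogit(X, d$case, d$stratum, d$animal_id)
  f$vcov_robust <- f$vcov_naive
  expect_equal(qic(f), -2 * f$quasi_ll + 2 * f$K, tolerance = 1e-9)
  # hand evaluation of the trace form
  tr <- sum(diag(solve(f$vcov_naive) %*% f$vcov_robust))
  expect_equal(qic(f), -2 * f$quasi_ll + 2 * tr, tolerance = 1e-12)
})

test_that("the five-model set matches the printed specifications", {
  cols <- as.data.frame(matrix(0, 2, 16))
  names(cols) <- c("StepLength", "lnStepLength", "DistRoads", "DistAspen",
                   "DistFor", "Elev", "TPI", "TRI", "ShrubHeight",
                   "BareGround", "Herb", "SageHeight", "IndirectLion",
                   "IndirectKill", "lnDirectLion", "lnDirectKill")
  specs <- build_model_set(cols)
  expect_identical(length(specs), 5L)
  expect_identical(length(specs$base), 12L)
  for (nm in setdiff(names(specs), "base"))
    expect_identical(length(specs[[nm]]), 14L)
  expect_true(all(!vapply(specs, anyDuplicated, 0L) > 0))
  cols$Elev <- NULL
  expect_error(build_model_set(cols), "Elev")
})

test_that("model ranking orders by QIC with zero delta at the top", {
  set.seed(12)
  obs <- data.frame(stratum = paste0("s", 1:60), animal_id = "C1",
                    t1 = season_start_test(), t2 = season_start_test() + 3600,
                    x1 = 0, y1 = 0, x2 = 100, y2 = 0,
                    length = 100, bearing = 0, prev_bearing = 0, turn = 0)
  d <- sample_available(obs, seed = 4)
  X <- matrix(rnorm(nrow(d) * 2), ncol = 2, dimnames = list(NULL, c("u", "v")))
  f <- fit_clogit(X, d$case, d$stratum, d$animal_id)
  r <- rank_models(list(m1 = f, m2 = f))
  expect_equal(r$delta_qic, c(0, 0))
  expect_equal(r$qic[1], min(r$qic))

  f_alt <- f; f_alt$strata_levels <- paste0("x", 1:60)
  expect_error(rank_models(list(m1 = f, m2 = f_alt)), "different strata")
  expect_error(rank_models(list(m1 = f)), "at least 2")
})
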