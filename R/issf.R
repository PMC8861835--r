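#' Build observed movement steps from a fix table
#'
#' A step joins two consecutive fixes whose gap matches the nominal fix
#' interval within tolerance; gaps split the track into bursts and no step
#' spans a gap. A stratum additionally needs a turning angle, which
#' requires the preceding step, so the first step of each contiguous burst
#' yields no stratum.
#'
#' @param track fix data frame (one animal).
#' @param interval_h nominal fix interval in hours (default 1).
#' @param tolerance_min accepted deviation from the interval, minutes.
#' @return data frame of observed steps with columns `stratum`,
#'   `animal_id`, `t1`, `t2`, `x1`, `y1`, `x2`, `y2`, `length`, `bearing`,
#'   `prev_bearing`, `turn`.
#' @export
build_steps <- function(track, interval_h = 1, tolerance_min = 5) {
  track <- track[order(track$t), , drop = FALSE]
  n <- nrow(track)
  if (n < 3L) {
    warning("fewer than 3 fixes; no strata can be formed")
    return(empty_steps())
  }
  gap <- hours_between(track$t[-n], track$t[-1L])
  ok <- abs(gap - interval_h) <= tolerance_min / 60
  # step i joins fix i -> i+1 when ok[i]; a stratum needs steps i-1 and i
  dx <- diff(track$x); dy <- diff(track$y)
  len <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  use <- which(ok[-1L] & ok[-length(ok)]) + 1L  # index of the step, needs prev step
  if (length(use) == 0L) {
    warning("no contiguous fix triples; no strata formed")
    return(empty_steps())
  }
  data.frame(
    stratum = paste0(track$animal_id[1L], "_s", seq_along(use)),
    animal_id = track$animal_id[1L],
    t1 = track$t[use], t2 = track$t[use + 1L],
    x1 = track$x[use], y1 = track$y[use],
    x2 = track$x[use + 1L], y2 = track$y[use + 1L],
    length = len[use], bearing = bearing[use],
    prev_bearing = bearing[use - 1L],
    turn = wrap_angle(bearing[use] - bearing[use - 1L]))
}

empty_steps <- function() {
  data.frame(stratum = character(0), animal_id = character(0),
             t1 = as.POSIXct(character(0), tz = "UTC"),
             t2 = as.POSIXct(character(0), tz = "UTC"),
             x1 = numeric(0), y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
             length = numeric(0), bearing = numeric(0),
             prev_bearing = numeric(0), turn = numeric(0))
}

#' Sample available steps for each observed step
#'
#' Draws `n` available steps per stratum: lengths from a gamma
#' distribution (defaults matching the observed coyote step-length fit,
#' shape 0.38, scale 1402.57) and turning angles uniform on (-pi, pi\]
#' relative to the previous observed bearing. If a landscape is supplied,
#' endpoints falling outside it are rejected and redrawn — the same rule
#' the track generator uses, so generation and inference share one
#' candidate distribution.
#'
#' @param obs_steps observed steps from [build_steps()].
#' @param n available steps per stratum (default 10).
#' @param gamma_shape,gamma_scale gamma parameters (> 0).
#' @param seed RNG seed.
#' @param landscape optional landscape for endpoint rejection.
#' @return data frame of observed (case = 1) plus available (case = 0)
#'   steps with the same geometry columns.
#' @export
sample_available <- function(obs_steps, n = 10, gamma_shape = 0.38,
                             gamma_scale = 1402.57, seed = 1,
                             landscape = NULL) {
  if (gamma_shape <= 0 || gamma_scale <= 0)
    stop("gamma parameters must be positive")
  rng <- local_rng(seed)
  ns <- nrow(obs_steps)
  m <- ns * n
  len <- rng$gamma(m, shape = gamma_shape, scale = gamma_scale)
  turn <- rng$unif(m, -pi, pi)
  prev <- rep(obs_steps$prev_bearing, each = n)
  x1 <- rep(obs_steps$x1, each = n); y1 <- rep(obs_steps$y1, each = n)
  ang <- wrap_angle(prev + turn)
  x2 <- x1 + len * cos(ang); y2 <- y1 + len * sin(ang)
  if (!is.null(landscape)) {
    for (it in seq_len(200L)) {
      bad <- which(!in_landscape(landscape, x2, y2))
      if (length(bad) == 0L) break
      len[bad] <- rng$gamma(length(bad), shape = gamma_shape, scale = gamma_scale)
      turn[bad] <- rng$unif(length(bad), -pi, pi)
      ang[bad] <- wrap_angle(prev[bad] + turn[bad])
      x2[bad] <- x1[bad] + len[bad] * cos(ang[bad])
      y2[bad] <- y1[bad] + len[bad] * sin(ang[bad])
    }
  }
  avail <- data.frame(
    stratum = rep(obs_steps$stratum, each = n),
    animal_id = rep(obs_steps$animal_id, each = n),
    t1 = rep(obs_steps$t1, each = n), t2 = rep(obs_steps$t2, each = n),
    x1 = x1, y1 = y1, x2 = x2, y2 = y2,
    length = len, bearing = ang,
    prev_bearing = prev, turn = turn)
  obs <- obs_steps
  obs$case <- 1L
  avail$case <- 0L
  out <- rbind(obs[, names(avail)], avail)
  out <- out[order(out$stratum, -out$case), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a conditional logistic (matched case-control) model
#'
#' Maximizes the stratified multinomial log-likelihood
#' `sum_s [eta_obs - ln sum_j exp(eta_j)]` by Newton-Raphson with step
#' halving. Returns the naive covariance (inverse observed information)
#' and the cluster-robust sandwich covariance with per-stratum scores
#' summed within cluster (here, within animal) — the estimator needed for
#' QIC model ranking on autocorrelated step data.
#'
#' @param X numeric design matrix (no intercept; it cancels within strata).
#' @param case 0/1 vector, exactly one 1 per stratum.
#' @param stratum stratum identifiers.
#' @param cluster cluster identifiers (e.g. animal id), one value per row.
#' @param tol relative score-norm convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `clogit_fit` with elements `coef`, `vcov_naive`,
#'   `vcov_robust`, `quasi_ll`, `K`, `qic`, `se`, `z`, `p`, `n_strata`,
#'   `strata_levels`, `iterations`.
#' @export
fit_clogit <- function(X, case, stratum, cluster, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  case <- as.integer(case)
  stratum <- as.character(stratum)
  cluster <- as.character(cluster)
  ones <- tapply(case, stratum, sum)
  if (any(ones != 1L)) stop("every stratum must contain exactly one observed case")
  K <- ncol(X)
  sf <- factor(stratum)
  cl_of_stratum <- tapply(cluster, sf, `[`, 1L)
  n_strata <- nlevels(sf)

  beta <- rep(0, K)
  ll_fun <- function(beta) {
    eta <- drop(X %*% beta)
    mx <- as.numeric(tapply(eta, sf, max)[sf])
    ex <- exp(eta - mx)
    denom <- drop(rowsum(ex, sf))
    p <- ex / denom[sf]
    ll <- sum(eta[case == 1L]) - sum(log(denom) + as.numeric(unique_by(mx, sf)))
    list(ll = ll, p = p)
  }
  st <- ll_fun(beta)
  for (it in seq_len(max_iter)) {
    p <- st$p
    XB <- rowsum(p * X, sf)                      # per-stratum E[x]
    grad <- colSums(X[case == 1L, , drop = FALSE]) - colSums(XB)
    info <- crossprod(sqrt(p) * X) - crossprod(XB)
    sc <- sqrt(sum(grad^2)) / max(1, n_strata)
    if (sc < tol) break
    delta <- tryCatch(solve(info, grad), error = function(e)
      stop("singular information matrix; check for collinear covariates"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      st_new <- ll_fun(cand)
      if (st_new$ll >= st$ll - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta + step * delta
    st <- st_new
    if (it == max_iter) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop(sprintf("conditional-logistic fit did not converge in %d iterations; possible separation in covariate '%s'",
                   max_iter, worst))
    }
  }
  if (any(abs(beta) > 10)) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop(sprintf("diverging coefficient suggests separation in covariate '%s'", worst))
  }
  p <- st$p
  XB <- rowsum(p * X, sf)
  info <- crossprod(sqrt(p) * X) - crossprod(XB)
  vn <- tryCatch(solve(info), error = function(e) {
    warning("information matrix is singular at the optimum; covariance from pseudo-inverse")
    pinv_sym(info)
  })
  # per-stratum scores, summed within cluster
  U <- rowsum(case * X, sf) - XB
  G <- rowsum(U, cl_of_stratum[rownames(U)])
  vr <- vn %*% crossprod(G) %*% vn
  vr <- (vr + t(vr)) / 2
  se <- sqrt(diag(vr))
  z <- beta / se
  fit <- structure(list(
    coef = stats::setNames(beta, colnames(X)),
    vcov_naive = vn, vcov_robust = vr,
    quasi_ll = st$ll, K = K,
    se_naive = stats::setNames(sqrt(diag(vn)), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    n_strata = n_strata,
    strata_levels = levels(sf),
    iterations = it), class = "clogit_fit")
  fit$qic <- tryCatch(qic(fit), error = function(e) NA_real_)
  fit
}

# first value of x within each level of f, in level order, as a vector
# aligned with tapply-style level output
unique_by <- function(x, f) tapply(x, f, `[`, 1L)

# Moore-Penrose inverse of a symmetric matrix
pinv_sym <- function(m, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  pos <- abs(e$values) > tol * max(abs(e$values), 1)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("<clogit_fit> %d strata, K = %d, quasi-LL = %.2f, QIC = %.2f\n",
              x$n_strata, x$K, x$quasi_ll, x$qic))
  print(data.frame(beta = round(x$coef, 4), se = round(x$se, 4),
                   z = round(x$z, 3), p = signif(x$p, 3)))
  invisible(x)
}

#' Quasi-likelihood under independence criterion
#'
#' `QIC = -2 Q + 2 trace(A V_r)` where `Q` is the quasi-log-likelihood,
#' `A` the naive (independence) information and `V_r` the cluster-robust
#' covariance (Pan 2001). When the robust and naive covariances coincide
#' the trace term reduces to `K` and QIC becomes `-2Q + 2K`.
#'
#' @param fit a `clogit_fit`.
#' @return scalar QIC.
#' @export
qic <- function(fit) {
  A <- tryCatch(solve(fit$vcov_naive), error = function(e)
    stop("singular naive covariance"))
  -2 * fit$quasi_ll + 2 * sum(diag(A %*% fit$vcov_robust))
}

#' The five candidate iSSF specifications
#'
#' The base model holds the movement terms (step length and its log) plus
#' the ten habitat covariates; the four augmented models add the printed
#' combinations of direct and indirect risk/reward terms:
#' direct kill + indirect lion, indirect-only, direct-only, and indirect
#' kill + direct lion.
#'
#' @param covariate_table data frame whose columns must include every
#'   referenced covariate.
#' @return named list of character vectors of covariate names.
#' @export
build_model_set <- function(covariate_table) {
  base <- c("StepLength", "lnStepLength", "DistRoads", "DistAspen", "DistFor",
            "Elev", "TPI", "TRI", "ShrubHeight", "BareGround", "Herb",
            "SageHeight")
  specs <- list(
    base = base,
    direct_kill_indirect_lion = c(base, "lnDirectKill", "IndirectLion"),
    indirect_only = c(base, "IndirectKill", "IndirectLion"),
    direct_only = c(base, "lnDirectKill", "lnDirectLion"),
    indirect_kill_direct_lion = c(base, "IndirectKill", "lnDirectLion"))
  need <- unique(unlist(specs))
  miss <- setdiff(need, names(covariate_table))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  specs
}

#' Rank fitted models by QIC
#'
#' @param fits named list of `clogit_fit` objects fit to the same strata.
#' @return data frame `model, quasi_ll, K, qic, delta_qic` sorted by QIC.
#' @export
rank_models <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits")
  strata <- lapply(fits, `[[`, "strata_levels")
  if (!all(vapply(strata[-1L], identical, TRUE, strata[[1L]])))
    stop("fits were made on different strata sets")
  tab <- data.frame(
    model = names(fits),
    quasi_ll = vapply(fits, `[[`, 0, "quasi_ll"),
    K = vapply(fits, `[[`, 0L, "K"),
    qic = vapply(fits, `[[`, 0, "qic"))
  tab$delta_qic <- tab$qic - min(tab$qic)
  tab <- tab[order(tab$qic), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
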