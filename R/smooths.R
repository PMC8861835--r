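#' Construct a penalized spline basis
#'
#' Thin wrapper over the standard penalized-regression-spline machinery:
#' `"bs"` gives a cubic B-spline basis (rows are a partition of unity)
#' with a second-derivative penalty whose null space contains linear
#' functions; `"cc"` a cyclic cubic basis wrapping at the supplied period
#' (e.g. 24 h for hour of day); `"re"` a random-intercept (ridge) basis.
#'
#' @param x covariate values (finite).
#' @param type `"bs"`, `"cc"` or `"re"` (`x` must be a factor for `"re"`).
#' @param k basis dimension (>= 3 and at most the number of distinct `x`).
#' @param period for `"cc"`, the wrap period; defaults to `range(x)`.
#' @return list with `X` (basis matrix), `S` (penalty matrix), `type`, `k`.
#' @export
build_basis <- function(x, type = c("bs", "cc", "re"), k = 10, period = NULL) {
  type <- match.arg(type)
  if (type != "re") {
    if (any(!is.finite(x))) stop("`x` must be finite")
    if (k < 3L) stop("`k` must be at least 3")
    if (k > length(unique(x)))
      stop("`k` exceeds the number of distinct covariate values")
  }
  dat <- data.frame(x = x)
  knots <- NULL
  if (type == "cc" && !is.null(period)) knots <- list(x = period)
  spec <- switch(type,
    bs = mgcv::s(x, bs = "bs", k = k),
    cc = mgcv::s(x, bs = "cc", k = k),
    re = mgcv::s(x, bs = "re"))
  sm <- mgcv::smoothCon(spec, data = dat, knots = knots,
                        absorb.cons = FALSE)[[1L]]
  list(X = sm$X, S = sm$S[[1L]], type = type, k = ncol(sm$X), smooth = sm)
}

#' Fit a penalized generalized additive model
#'
#' The shared engine behind the movement-rate and kill-site-use analyses:
#' penalized IRLS with smoothing parameters chosen by GCV (default) or
#' REML, gamma (log link) or binomial (logit) families, random intercepts
#' as ridge-penalized terms, and offsets entering the linear predictor as
#' logs of the supplied columns.
#'
#' @param data data frame.
#' @param response response column name.
#' @param smooths list of `list(var =, bs =, k =)` smooth specifications
#'   (`bs` as in mgcv, e.g. `"tp"`, `"bs"`, `"cc"`).
#' @param linear character vector of parametric term names.
#' @param offsets character vector of columns whose logs are summed into
#'   the linear predictor (must be positive).
#' @param family `"gamma"` (log link) or `"binomial"` (logit).
#' @param random character vector of grouping columns entered as
#'   random-intercept terms (coerced to factor); list them outermost
#'   first when nested.
#' @param method smoothing-parameter criterion, `"GCV.Cp"` or `"REML"`.
#' @param knots passed to [mgcv::gam()] (e.g. cyclic endpoints).
#' @param sp optional fixed smoothing parameters (bypass GCV/REML).
#' @return object of class `pgam_fit`: list with the underlying `gam`
#'   object, `edf` (per smooth), `p_smooth`, `aic`, `deviance`, `family`,
#'   and the term bookkeeping used by [predict_with_ci()].
#' @export
fit_pgam <- function(data, response, smooths = list(), linear = character(0),
                     offsets = character(0), family = c("gamma", "binomial"),
                     random = character(0), method = "GCV.Cp", knots = NULL,
                     sp = NULL) {
  family <- match.arg(family)
  fam <- switch(family,
                gamma = stats::Gamma(link = "log"),
                binomial = stats::binomial(link = "logit"))
  for (r in random) data[[r]] <- factor(data[[r]])
  sm_terms <- vapply(smooths, function(s)
    sprintf("s(%s, bs = \"%s\", k = %d)", s$var, s$bs %||% "tp",
            as.integer(s$k %||% 10)), "")
  re_terms <- sprintf("s(%s, bs = \"re\")", random)
  off_terms <- character(0)
  if (length(offsets)) {
    data$.offset <- rowSums(log(as.matrix(data[, offsets, drop = FALSE])))
    off_terms <- "offset(.offset)"
  }
  rhs <- c(sm_terms, re_terms, linear, off_terms)
  if (length(rhs) == 0L) rhs <- "1"
  form <- stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  g <- mgcv::gam(form, family = fam, data = data, method = method,
                 knots = knots, select = FALSE, sp = sp)
  if (!g$converged) stop("penalized IRLS did not converge")
  s_tab <- summary(g)$s.table
  structure(list(
    gam = g, formula = form,
    edf = if (!is.null(s_tab)) stats::setNames(s_tab[, "edf"], rownames(s_tab)),
    p_smooth = if (!is.null(s_tab)) stats::setNames(s_tab[, ncol(s_tab)], rownames(s_tab)),
    aic = stats::AIC(g), deviance = stats::deviance(g),
    family = family, random = random, offsets = offsets,
    smooths = smooths, linear = linear, response = response),
    class = "pgam_fit")
}

#' @export
print.pgam_fit <- function(x, ...) {
  cat(sprintf("<pgam_fit> %s family, AIC = %.1f\n", x$family, x$aic))
  if (!is.null(x$edf)) {
    for (nm in names(x$edf))
      cat(sprintf("  %s: EDF = %.3f, p = %.3g\n", nm, x$edf[nm], x$p_smooth[nm]))
  }
  invisible(x)
}

#' Backwards stepwise elimination by AIC
#'
#' Refits the model repeatedly, at each step removing the removable term
#' whose removal most decreases AIC, and stopping when no removal
#' decreases it. The elimination log records each candidate's change in
#' AIC relative to the model containing it.
#'
#' @param data,response,smooths,linear,offsets,family,random,method,knots
#'   as in [fit_pgam()].
#' @param removable character vector of `linear` term names eligible for
#'   removal.
#' @return list with `fit` (the final `pgam_fit`), `retained`, and `log`
#'   (data frame `step, term, delta_aic, removed`; `delta_aic` is the AIC
#'   of the model with the term minus the model without it).
#' @export
backwards_aic <- function(data, response, smooths = list(),
                          linear = character(0), removable = character(0),
                          offsets = character(0), family = "gamma",
                          random = character(0), method = "GCV.Cp",
                          knots = NULL) {
  fit <- fit_pgam(data, response, smooths, linear, offsets, family, random,
                  method, knots)
  log_ <- data.frame(step = integer(0), term = character(0),
                     delta_aic = numeric(0), removed = logical(0))
  step <- 0L
  repeat {
    cand <- intersect(removable, linear)
    if (length(cand) == 0L) break
    step <- step + 1L
    aics <- vapply(cand, function(tm) {
      f <- fit_pgam(data, response, smooths, setdiff(linear, tm), offsets,
                    family, random, method, knots)
      f$aic
    }, 0)
    deltas <- fit$aic - aics  # > 0 means removal improves (lowers) AIC
    best <- which.max(deltas)
    log_ <- rbind(log_, data.frame(step = step, term = cand[best],
                                   delta_aic = unname(deltas[best]),
                                   removed = deltas[best] > 0))
    if (deltas[best] <= 0) break
    linear <- setdiff(linear, cand[best])
    removable <- setdiff(removable, cand[best])
    fit <- fit_pgam(data, response, smooths, linear, offsets, family, random,
                    method, knots)
  }
  list(fit = fit, retained = linear, log = log_)
}

#' Response-scale predictions with 95% confidence intervals
#'
#' Normal intervals on the linear predictor mapped through the inverse
#' link. Random-intercept terms are excluded by default so curves are
#' population-level. Offset columns must be present in `newdata`
#' (reference values chosen by the caller). Covariates outside the fitted
#' range trigger an extrapolation warning.
#'
#' @param fit a `pgam_fit`.
#' @param newdata data frame of covariates.
#' @param exclude_random exclude random-effect terms (default TRUE).
#' @return `newdata` with columns `fit`, `lo`, `hi` appended.
#' @export
predict_with_ci <- function(fit, newdata, exclude_random = TRUE) {
  g <- fit$gam
  need <- c(vapply(fit$smooths, `[[`, "", "var"), fit$linear)
  miss <- setdiff(need, names(newdata))
  if (length(miss))
    stop("unknown or missing covariate(s) in newdata: ",
         paste(miss, collapse = ", "))
  for (s in fit$smooths) {
    v <- s$var
    if (v %in% names(newdata)) {
      r <- range(g$model[[v]], na.rm = TRUE)
      if (any(newdata[[v]] < r[1L] | newdata[[v]] > r[2L]))
        warning(sprintf("extrapolating beyond fitted range of '%s'", v))
    }
  }
  if (length(fit$offsets)) {
    miss <- setdiff(fit$offsets, names(newdata))
    if (length(miss)) stop("newdata must contain offset column(s): ",
                           paste(miss, collapse = ", "))
    newdata$.offset <- rowSums(log(as.matrix(newdata[, fit$offsets, drop = FALSE])))
  }
  excl <- NULL
  if (exclude_random && length(fit$random)) {
    excl <- sprintf("s(%s)", fit$random)
    for (r in fit$random) {
      if (!r %in% names(newdata))
        newdata[[r]] <- factor(levels(g$model[[r]])[1L],
                               levels = levels(g$model[[r]]))
    }
  }
  pr <- mgcv::predict.gam(g, newdata = newdata, type = "link", se.fit = TRUE,
                          exclude = excl, newdata.guaranteed = FALSE)
  inv <- g$family$linkinv
  newdata$fit <- as.numeric(inv(pr$fit))
  newdata$lo <- as.numeric(inv(pr$fit - 1.96 * pr$se.fit))
  newdata$hi <- as.numeric(inv(pr$fit + 1.96 * pr$se.fit))
  newdata
}
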