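#' Direct risk/reward metric: minimum distance-by-time-since product
#'
#' For each query location/time, evaluates distance (km) to every past
#' source event multiplied by time since that event (days) and returns the
#' minimizing source. The minimum of the product identifies the most
#' spatiotemporally relevant source of risk (lion locations) or reward
#' (kill sites). Distances are floored at 1 m (0.001 km) and elapsed times
#' at 60 s before multiplying so the natural log is always defined;
#' queries with no past source get `NA` (their design rows are dropped
#' downstream and logged).
#'
#' @param query data frame with columns `t` (POSIXct), `x`, `y` (m).
#' @param sources data frame with columns `t`, `x`, `y`; each event is
#'   usable only for queries at or after its time.
#' @param dist_floor_km,dt_floor_days positivity floors.
#' @return data frame with `value` (km.days), `ln_value`, `source`
#'   (minimizing row index into `sources`), `dist_km`, `dt_days`, and
#'   `n_floored` attribute counting floored components.
#' @export
direct_metric <- function(query, sources, dist_floor_km = 0.001,
                          dt_floor_days = 60 / 86400) {
  if (nrow(sources) == 0L) stop("`sources` must be non-empty")
  ord <- order(sources$t)
  st <- as.numeric(sources$t[ord]); sx <- sources$x[ord]; sy <- sources$y[ord]
  qt <- as.numeric(query$t)
  n_past <- findInterval(qt, st)  # sources with t_source <= t_query
  out <- data.frame(value = rep(NA_real_, nrow(query)), ln_value = NA_real_,
                    source = NA_integer_, dist_km = NA_real_, dt_days = NA_real_)
  n_floored <- 0L
  for (i in seq_len(nrow(query))) {
    k <- n_past[i]
    if (k == 0L) next
    d <- sqrt((query$x[i] - sx[seq_len(k)])^2 + (query$y[i] - sy[seq_len(k)])^2) / 1000
    dt <- (qt[i] - st[seq_len(k)]) / 86400
    n_floored <- n_floored + sum(d < dist_floor_km) + sum(dt < dt_floor_days)
    d <- pmax(d, dist_floor_km)
    dt <- pmax(dt, dt_floor_days)
    v <- d * dt
    j <- which.min(v)
    out$value[i] <- v[j]; out$ln_value[i] <- log(v[j])
    out$source[i] <- ord[j]; out$dist_km[i] <- d[j]; out$dt_days[i] <- dt[j]
  }
  attr(out, "n_floored") <- n_floored
  out
}

#' Natural log of a direct metric value
#'
#' The log of the km.days product reflects the reduced behavioural effect
#' of sources at larger spatiotemporal scales.
#'
#' @param value positive metric value(s) on the km.days scale.
#' @return natural logarithm.
#' @export
ln_direct <- function(value) {
  if (any(value <= 0, na.rm = TRUE)) stop("metric values must be positive")
  log(value)
}

#' Summarize the chosen components of direct metrics
#'
#' Descriptive summary (mean and range) of the time-since and distance of
#' the minimizing sources across query fixes, in the reporting units used
#' for the field system (days, km).
#'
#' @param metrics data frame from [direct_metric()].
#' @return list with `mean_dt_days`, `range_dt_days`, `mean_dist_km`,
#'   `range_dist_km`, `n`.
#' @export
summarize_chosen <- function(metrics) {
  m <- metrics[!is.na(metrics$value), , drop = FALSE]
  if (nrow(m) == 0L) stop("no non-missing metrics")
  list(mean_dt_days = mean(m$dt_days), range_dt_days = range(m$dt_days),
       mean_dist_km = mean(m$dist_km), range_dist_km = range(m$dist_km),
       n = nrow(m))
}
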