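euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# wrap an angle to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

hours_between <- function(t1, t2) as.numeric(difftime(t2, t1, units = "hours"))

days_between <- function(t1, t2) as.numeric(difftime(t2, t1, units = "days"))

season_start <- function(year = 2019) {
  as.POSIXct(sprintf("%d-05-15 00:00:00", year), tz = "UTC")
}

#' Write and read GPS fix tables
#'
#' The fix CSV interchange format has columns
#' `animal_id, species, iso8601_utc, x, y` with projected coordinates in
#' metres.
#'
#' @param fixes data frame with columns `animal_id`, `species`, `t`
#'   (POSIXct, UTC), `x`, `y`.
#' @param path file path.
#' @export
write_fix_csv <- function(fixes, path) {
  out <- data.frame(
    animal_id = fixes$animal_id,
    species = fixes$species,
    iso8601_utc = format(fixes$t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = fixes$x, y = fixes$y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fix_csv
#' @return `read_fix_csv` returns the fix data frame with a POSIXct `t`.
#' @export
read_fix_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    animal_id = d$animal_id, species = d$species,
    t = as.POSIXct(d$iso8601_utc, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = d$x, y = d$y)
}
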