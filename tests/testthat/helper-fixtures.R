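# shared small fixtures, built once per test run

tiny_land <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- add_terrain_layers(gen_landscape(42, extent = 64))
    cache
  }
})

# a landscape whose cover layer is entirely one class
uniform_cover_land <- function(class = 2L, extent = 40L, resolution = 30) {
  land <- gen_landscape(7, extent = extent, resolution = resolution)
  land$layers$cover <- matrix(class, land$ny, land$nx)
  land
}

# hand-built fix table on an hourly schedule
make_fixes <- function(xy, t0 = season_start_test(), interval_h = 1,
                       id = "C1", species = "coyote") {
  data.frame(animal_id = id, species = species,
             t = t0 + (seq_len(nrow(xy)) - 1L) * interval_h * 3600,
             x = xy[, 1L], y = xy[, 2L])
}

season_start_test <- function() as.POSIXct("2019-05-15 00:00:00", tz = "UTC")

# brute-force O(n.m) encounter pair oracle
brute_pairs <- function(ct, lt, dist_km = 1, dt_h = 2) {
  out <- list()
  for (i in seq_len(nrow(ct))) for (j in seq_len(nrow(lt))) {
    d <- sqrt((ct$x[i] - lt$x[j])^2 + (ct$y[i] - lt$y[j])^2)
    dt <- abs(as.numeric(difftime(ct$t[i], lt$t[j], units = "hours")))
    if (d <= dist_km * 1000 && dt <= dt_h)
      out[[length(out) + 1L]] <- c(i = i, j = j)
  }
  if (length(out)) do.call(rbind, out) else matrix(0L, 0L, 2L)
}

# brute-force direct-metric oracle (linear scan over all past sources)
brute_direct <- function(qt, qx, qy, src, dist_floor = 0.001, dt_floor = 60 / 86400) {
  past <- src[as.numeric(src$t) <= as.numeric(qt), , drop = FALSE]
  if (nrow(past) == 0L) return(NA_real_)
  best <- Inf
  for (j in seq_len(nrow(past))) {
    d <- max(sqrt((qx - past$x[j])^2 + (qy - past$y[j])^2) / 1000, dist_floor)
    dt <- max((as.numeric(qt) - as.numeric(past$t[j])) / 86400, dt_floor)
    best <- min(best, d * dt)
  }
  best
}
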