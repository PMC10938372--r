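# shared fixtures, all generated in code

hourly_series <- function(n_hours = 48, pm = NULL, station_id = "s1") {
  tm <- seq(as.POSIXct("2021-07-01 00:00:00", tz = "UTC"),
            by = "hour", length.out = n_hours)
  if (is.null(pm)) pm <- seq_len(n_hours) - 1
  monitor_series(
    tibble::tibble(time = tm, pm1 = pm * 0.9, pm25 = pm, pm10 = pm * 1.03,
                   temperature = 15, relative_humidity = 80),
    station_id = station_id, latitude = 51.32, longitude = -0.56,
    step = "hour"
  )
}

daily_series <- function(days = 30, pm25 = NULL, station_id = "s1",
                         x = 0, y = 0, start = "2021-07-01") {
  tm <- seq(as.Date(start), by = "day", length.out = days)
  if (is.null(pm25)) pm25 <- 8 + sin(seq_len(days) / 3)
  ms <- monitor_series(
    tibble::tibble(time = tm, pm1 = pm25 * 0.93, pm25 = pm25,
                   pm10 = pm25 * 1.03,
                   temperature = 14 + cos(seq_len(days) / 5),
                   relative_humidity = 80 + 5 * sin(seq_len(days) / 7)),
    station_id = station_id, latitude = 51.32, longitude = -0.56,
    step = "day"
  )
  attr(ms, "x") <- x
  attr(ms, "y") <- y
  ms
}

tiny_met <- function(days = 30, seed = 42, start = "2021-07-01") {
  simulate_met(days, seed = seed, start = as.Date(start))
}

# small complete study inputs shared by features/model/mapping tests
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      town <- make_town(town_config(), seed = 301)
      met <- simulate_met(40, seed = 302)
      sim <- suppressMessages(simulate_pm(town, met, noise_sd = 0.1,
                                          seed = 303))
      raster <- rasterize_roads(town$roads, resolution = 4)
      cache <<- list(town = town, met = met, sim = sim, raster = raster)
    }
    cache
  }
})

write_monitor_fixture_csv <- function(path, rows) {
  writeLines(c("time,pm1,pm25,pm10,temperature,relative_humidity", rows), path)
}
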