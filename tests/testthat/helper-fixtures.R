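# Small hand-built fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# A release point with towers placed at exact bearings/distances from it.
fx_release <- list(lat = 37.2, lon = -75.93)

fx_tower_at <- function(id, bearing, dist_km, water_body = NA_character_,
                        side = NA_character_) {
  p <- destination_point(fx_release$lat, fx_release$lon, bearing, dist_km)
  data.frame(tower_id = id, lat = p$lat, lon = p$lon,
             water_body = water_body, side = side, stringsAsFactors = FALSE)
}

fx_deployment <- function(tag_id = "t1",
                          release_time = utc("2021-09-01 23:30:00")) {
  data.frame(tag_id = tag_id, species = "LABO", sex = "female", age = "adult",
             release_time = release_time,
             release_lat = fx_release$lat, release_lon = fx_release$lon,
             tag_life_days = 30, stringsAsFactors = FALSE)
}

fx_detections <- function(tag_id, times, tower_ids, antenna_id = "a1",
                          signal = -60, run_length = 10L) {
  data.frame(tag_id = tag_id, timestamp = times, tower_id = tower_ids,
             antenna_id = antenna_id,
             signal_strength = rep_len(signal, length(times)),
             run_length = rep_len(as.integer(run_length), length(times)),
             stringsAsFactors = FALSE)
}

# Constant-weather table (one station at the release point) covering a date
# range; handy for covariate tests where the expected value must be forced.
fx_weather <- function(start, end, temperature = 18, wind_speed = 3,
                       wind_dir = 90, pressure = 101.3, precipitation = 0,
                       visibility = 16) {
  hours <- seq(utc(start), utc(end), by = "hour")
  w <- data.frame(station_id = "s1", timestamp = hours,
                  temperature = temperature, wind_speed = wind_speed,
                  wind_dir = wind_dir, pressure = pressure,
                  precipitation = precipitation, visibility = visibility,
                  stringsAsFactors = FALSE)
  attr(w, "stations") <- data.frame(station_id = "s1", lat = fx_release$lat,
                                    lon = fx_release$lon,
                                    stringsAsFactors = FALSE)
  w
}

# Deterministic use-availability rows from the logistic model
# eta = b0 + b . x, for mixed-logit correctness tests.
fx_logit_rows <- function(n = 200, n_tags = 8, beta = c(-1, 0.8, -0.5),
                         sd_tag = 0.7, seed = 42) {
  set.seed(seed)
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  tag <- sample(sprintf("tg%02d", seq_len(n_tags)), n, replace = TRUE)
  b <- rnorm(n_tags, 0, sd_tag)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2 + b[as.integer(factor(tag))]
  data.frame(tag_id = tag, used = rbinom(n, 1, plogis(eta)),
             x1 = x1, x2 = x2, stringsAsFactors = FALSE)
}
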