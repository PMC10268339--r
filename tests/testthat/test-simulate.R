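small_cfg <- function(seed = 3, ...) {
  scenario_config(seed = seed,
                  n_bats = c(resident = 2L, migrant = 2L, crosser = 2L,
                             returner = 1L), ...)
}

test_that("every stage is reproducible from (seed, config)", {
  cfg <- small_cfg(seed = 9)
  w1 <- simulate_weather(cfg)
  w2 <- simulate_weather(cfg)
  expect_identical(w1, w2)
  tw <- simulate_towers(cfg)
  b1 <- simulate_bats(cfg, tw, w1)
  b2 <- simulate_bats(cfg, tw, w1)
  expect_identical(b1, b2)
  d1 <- simulate_detections(b1$positions, tw, cfg)
  d2 <- simulate_detections(b2$positions, tw, cfg)
  expect_identical(d1, d2)
  # and byte-identical on disk
  dir <- withr::local_tempdir()
  write_detections(d1, file.path(dir, "a.csv"))
  write_detections(d2, file.path(dir, "b.csv"))
  expect_identical(unname(tools::md5sum(file.path(dir, "a.csv"))),
                   unname(tools::md5sum(file.path(dir, "b.csv"))))
})

test_that("weather respects physical bounds over a long horizon", {
  cfg <- scenario_config(seed = 5, study_start = as.Date("2021-06-01"),
                         study_end = as.Date("2022-08-01"))
  w <- simulate_weather(cfg)
  expect_gt(nrow(w), 10000)
  expect_true(all(w$wind_speed >= 0))
  expect_true(all(w$visibility >= 0 & w$visibility <= 16))
  expect_true(all(w$precipitation >= 0))
  expect_true(all(w$wind_dir >= 0 & w$wind_dir < 360))
  expect_error(simulate_weather(scenario_config(seed = 1,
                                                study_end = as.Date("2021-08-16"),
                                                study_start = as.Date("2021-08-15"))),
               NA)
})

test_that("temperature noise keeps its AR(1) persistence", {
  cfg <- scenario_config(seed = 11)
  w <- simulate_weather(cfg)
  w1 <- w[w$station_id == w$station_id[1], ]
  # strip the deterministic structure the generator declares, then check
  # the residual lag-1 autocorrelation implied by the AR coefficient
  start <- min(w1$timestamp)
  day_frac <- as.numeric(difftime(w1$timestamp, start, units = "days"))
  season <- 24 - 12 * day_frac / max(day_frac)
  st <- attr(w, "stations")
  hloc <- (as.numeric(w1$timestamp) / 3600 + st$lon[1] / 15) %% 24
  diurnal <- 4 * cos(2 * pi * (hloc - 15) / 24)
  resid <- w1$temperature - season - diurnal
  expect_gt(stats::cor(resid[-1], resid[-length(resid)]), 0.5)
})

test_that("archetype trajectories obey their constraints", {
  cfg <- small_cfg(seed = 13)
  tw <- simulate_towers(cfg)
  w <- simulate_weather(cfg)
  b <- simulate_bats(cfg, tw, w)
  for (tag in names(b$truth)) {
    tr <- b$truth[[tag]]
    pos <- b$positions[b$positions$tag_id == tag, ]
    dep <- b$deployments[b$deployments$tag_id == tag, ]
    d <- haversine_km(pos$lat, pos$lon, dep$release_lat, dep$release_lon)
    if (tr$archetype == "resident") {
      expect_lt(max(d), 12)
    }
    if (tr$archetype == "migrant") {
      last <- pos[nrow(pos), ]
      expect_gt(max(d), 50)
      brg <- initial_bearing_deg(dep$release_lat, dep$release_lon,
                                 last$lat, last$lon)
      expect_lt(abs(((brg - tr$heading + 180) %% 360) - 180), 25)
    }
    if (tr$archetype == "returner") {
      expect_gt(max(d), 50)
      expect_lt(d[length(d)], 12)
    }
    # all truth hours within the simulated tag life
    expect_true(all(pos$timestamp >= dep$release_time - 3600))
    expect_true(all(pos$timestamp <=
                      dep$release_time + dep$tag_life_days * 86400 + 3600))
  }
})

test_that("an impossible crossing propensity yields zero crossing nights", {
  cfg <- small_cfg(seed = 17,
                   crossing_beta = c(intercept = -Inf,
                                     hours_since_sunset = 0,
                                     wind_speed = 0, temperature = 0))
  tw <- simulate_towers(cfg)
  w <- simulate_weather(cfg)
  b <- simulate_bats(cfg, tw, w)
  n_cross <- sum(vapply(b$truth, function(x) length(x$true_crossing_nights),
                        0L))
  expect_identical(n_cross, 0L)
  expect_error(simulate_bats(scenario_config(
    seed = 1, n_bats = c(resident = 0L, migrant = 0L, crosser = 0L,
                         returner = 0L)), tw, w), "zero")
})

test_that("detections decay with distance and stop beyond range", {
  cfg <- scenario_config(seed = 19)
  tower <- data.frame(tower_id = "T", lat = 37.0, lon = -76.0,
                      water_body = NA_character_, side = NA_character_,
                      stringsAsFactors = FALSE)
  mk_pos <- function(dist_km) {
    p <- destination_point(37.0, -76.0, 90, dist_km)
    data.frame(tag_id = "t1",
               timestamp = utc("2021-09-01 00:00:00") + (1:500) * 3600,
               lat = p$lat, lon = p$lon, state = "rest",
               stringsAsFactors = FALSE)
  }
  d1 <- simulate_detections(mk_pos(1), tower, cfg)
  d10 <- simulate_detections(mk_pos(10), tower, cfg)
  d50 <- simulate_detections(mk_pos(50), tower, cfg)
  expect_identical(nrow(d50), 0L)
  expect_gt(mean(d1$signal_strength), mean(d10$signal_strength))
  # every detection run is stamped within its source hour
  expect_true(all(d1$run_length >= 1))
})

test_that("detection timestamps stay within each tag's simulated life", {
  cfg <- small_cfg(seed = 23)
  sc <- simulate_scenario(cfg)
  real <- sc$detections[sc$detections$tower_id != "far_west", ]
  for (tag in unique(real$tag_id)) {
    dep <- sc$deployments[sc$deployments$tag_id == tag, ]
    tms <- real$timestamp[real$tag_id == tag]
    expect_true(all(tms >= dep$release_time - 3600))
    expect_true(all(tms <= dep$release_time + dep$tag_life_days * 86400 +
                      7200))
  }
})

test_that("the known-truth activity series generator is seed-stable and separable", {
  cfg <- scenario_config(seed = 1)
  a <- simulate_hmm_series(cfg, n_hours = 300, seed = 5)
  b <- simulate_hmm_series(cfg, n_hours = 300, seed = 5)
  expect_identical(a, b)
  expect_gt(mean(a$series$value[a$states == "active"]),
            mean(a$series$value[a$states == "rest"]))
})
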