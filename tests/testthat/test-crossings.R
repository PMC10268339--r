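# Crossing fixtures: two towers on opposite shores of a labelled bay, both
# close to the release point so the night clock is shared.

cx_towers <- rbind(
  fx_tower_at("east_t", 170, 4, "bay", "east"),
  fx_tower_at("west_t", 250, 35, "bay", "west")
)
cx_dep <- fx_deployment(release_time = utc("2021-09-01 22:00:00"))

cx_det <- function(times, tower_ids) {
  fx_detections("t1", utc(times), tower_ids)
}

test_that("a same-night opposite-shore pair yields one rounded midpoint", {
  # 20:00 local is roughly 00:00-01:00 UTC at this longitude; use UTC
  # instants within one night: sunset ~23:10 UTC on Sep 2
  det <- cx_det(c("2021-09-03 00:00:00", "2021-09-03 03:00:00"),
                c("east_t", "west_t"))
  ev <- detect_crossings(det, cx_towers, cx_dep)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$departure_tower, "east_t")
  expect_identical(ev$arrival_tower, "west_t")
  # midpoint 01:30 rounds half-up to 02:00
  expect_identical(as.numeric(ev$midpoint_hour),
                   as.numeric(utc("2021-09-03 02:00:00")))
  # departure is the *last* origin-side detection before the switch
  det2 <- cx_det(c("2021-09-03 00:00:00", "2021-09-03 01:00:00",
                   "2021-09-03 03:00:00"),
                 c("east_t", "east_t", "west_t"))
  ev2 <- detect_crossings(det2, cx_towers, cx_dep)
  expect_identical(nrow(ev2), 1L)
  expect_identical(as.numeric(ev2$departure_time),
                   as.numeric(utc("2021-09-03 01:00:00")))
})

test_that("opposite shores on different nights do not make a crossing", {
  det <- cx_det(c("2021-09-03 00:00:00", "2021-09-04 00:30:00"),
                c("east_t", "west_t"))
  expect_identical(nrow(detect_crossings(det, cx_towers, cx_dep)), 0L)
})

test_that("an out-and-back transit in one night yields two events", {
  det <- cx_det(c("2021-09-03 01:00:00", "2021-09-03 03:00:00",
                  "2021-09-03 06:30:00"),
                c("east_t", "west_t", "east_t"))
  ev <- detect_crossings(det, cx_towers, cx_dep)
  expect_identical(nrow(ev), 2L)
  expect_identical(ev$departure_tower, c("east_t", "west_t"))
})

test_that("crossing detection needs both shores labelled", {
  one_side <- cx_towers
  one_side$side <- "east"
  det <- cx_det(c("2021-09-03 00:00:00", "2021-09-03 03:00:00"),
                c("east_t", "west_t"))
  expect_identical(nrow(detect_crossings(det, one_side, cx_dep)), 0L)

  unlabeled <- cx_towers
  unlabeled$side[2] <- NA
  expect_warning(ev <- detect_crossings(det, unlabeled, cx_dep), "west_t")
  expect_identical(nrow(ev), 0L)
})

test_that("availability sampling is exact, seeded, and windowed", {
  ev <- data.frame(
    tag_id = rep(sprintf("t%d", 1:5), c(10, 10, 10, 5, 4)),
    midpoint_hour = utc("2021-09-03 02:00:00") + (1:39) * 86400 / 2,
    stringsAsFactors = FALSE
  )
  deps <- do.call(rbind, lapply(sprintf("t%d", 1:5), fx_deployment))
  av <- sample_available(ev, deps, ratio = 10, horizon_days = 40, seed = 4)
  expect_identical(nrow(av), 390L)
  # per-tag 10x
  expect_identical(as.integer(table(av$tag_id)[sprintf("t%d", 1:5)]),
                   c(100L, 100L, 100L, 50L, 40L))
  # within [release, release + 40 d], on whole hours, never a used hour
  for (tg in unique(av$tag_id)) {
    rel <- deps$release_time[deps$tag_id == tg]
    tms <- av$timestamp[av$tag_id == tg]
    expect_true(all(tms >= rel & tms <= rel + 40 * 86400))
    expect_true(all(as.numeric(tms) %% 3600 == 0))
    expect_false(any(as.numeric(tms) %in%
                       as.numeric(ev$midpoint_hour[ev$tag_id == tg])))
  }
  expect_identical(sample_available(ev, deps, seed = 4), av)
  expect_identical(nrow(sample_available(ev[0, ], deps, seed = 4)), 0L)
  expect_error(sample_available(ev, deps, ratio = 0.5), "ratio")
  # pooled alternative: same total, spread evenly over contributing tags
  avp <- sample_available(ev, deps, ratio = 10, seed = 4, pooled = TRUE)
  expect_identical(nrow(avp), 390L)
  expect_identical(as.integer(table(avp$tag_id)[sprintf("t%d", 1:5)]),
                   c(78L, 78L, 78L, 78L, 78L))
})

test_that("covariates follow the declared sign and delta conventions", {
  w <- fx_weather("2021-08-30 00:00:00", "2021-09-05 23:00:00",
                  wind_speed = 5, wind_dir = 90)
  ev <- data.frame(tag_id = "t1",
                   midpoint_hour = utc("2021-09-03 02:00:00"),
                   stringsAsFactors = FALSE)
  rows <- attach_covariates(ev, NULL, fx_deployment(), w)
  # wind blowing FROM the east: positive zonal component
  expect_equal(rows$wind_x, 5, tolerance = 1e-12)
  expect_equal(rows$wind_y, 0, tolerance = 1e-12)
  expect_equal(rows$d_wind_1h, 0)
  expect_equal(rows$d_temp_1h, 0)
  expect_equal(rows$used, 1L)

  w2 <- fx_weather("2021-08-30 00:00:00", "2021-09-05 23:00:00",
                   wind_speed = 5, wind_dir = 0)
  rows2 <- attach_covariates(ev, NULL, fx_deployment(), w2)
  expect_equal(rows2$wind_y, 5, tolerance = 1e-12)
  expect_equal(rows2$wind_x, 0, tolerance = 1e-12)

  # nightly pressure means 101.3 then 101.8 -> +0.5
  w3 <- fx_weather("2021-08-30 00:00:00", "2021-09-05 23:00:00")
  night2 <- night_id(w3$timestamp, fx_release$lat, fx_release$lon) ==
    as.Date("2021-09-02") & is_night(w3$timestamp, fx_release$lat,
                                     fx_release$lon)
  w3$pressure[night2] <- 101.8
  w3$pressure[!night2] <- 101.3
  rows3 <- attach_covariates(ev, NULL, fx_deployment(), w3)
  expect_equal(rows3$d_pressure_24h, 0.5)

  # missing weather hour names the timestamp
  w4 <- w[w$timestamp != utc("2021-09-03 02:00:00"), ]
  attr(w4, "stations") <- attr(w, "stations")
  expect_error(attach_covariates(ev, NULL, fx_deployment(), w4),
               "2021-09-03T02:00:00Z")
})
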