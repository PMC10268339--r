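# Classification fixtures are built around exact tower placements so every
# threshold (50 km migration, 12 km residency/return, > 1 night) is
# exercised at and just beyond its boundary.

# "home" sits 10 m from the release point, so tower-to-tower distances can
# differ from release-to-tower distances by up to that much; boundary
# placements leave a margin larger than the offset
bh_towers <- rbind(
  fx_tower_at("home", 0, 0.01),
  fx_tower_at("at50", 120, 49.95),
  fx_tower_at("past50", 120, 50.30),
  fx_tower_at("far60", 120, 60),
  fx_tower_at("near_home", 45, 5),
  fx_tower_at("at12", 200, 12.001),
  fx_tower_at("in12", 200, 11.999),
  fx_tower_at("out30", 200, 30)
)
bh_dep <- fx_deployment()

bh_track <- function(tower_ids, hours_after = seq_along(tower_ids) * 24) {
  fx_detections("t1", bh_dep$release_time + hours_after * 3600, tower_ids)
}

test_that("migration is a strict >50 km displacement without return", {
  expect_identical(classify_migration(bh_track(c("home", "far60")), bh_towers),
                   "migrant")
  expect_identical(classify_migration(bh_track(c("home", "out30")), bh_towers),
                   "neither")
  # at the threshold (not strictly greater): no migration
  expect_identical(classify_migration(bh_track(c("home", "at50")), bh_towers),
                   "neither")
  expect_identical(classify_migration(bh_track(c("home", "past50")), bh_towers),
                   "migrant")
  # out and back near the origin: a long-distance return, not migration
  expect_identical(
    classify_migration(bh_track(c("home", "far60", "near_home")), bh_towers),
    "long_distance_return")
  expect_error(classify_migration(bh_track("home")[0, ], bh_towers),
               "no detections")
})

test_that("the return radius bounds what counts as coming back", {
  # return to just inside 12 km of the origin tower vs just outside
  tw <- rbind(bh_towers, fx_tower_at("ret_at", 45, 11.95),
              fx_tower_at("ret_out", 45, 12.60))
  expect_identical(
    classify_migration(bh_track(c("home", "far60", "ret_at")), tw),
    "long_distance_return")
  expect_identical(
    classify_migration(bh_track(c("home", "far60", "ret_out")), tw),
    "migrant")
})

test_that("residency needs local towers across more than one night", {
  # nights 0 and 14 (the second before local midnight): 14 residency days
  det <- bh_track(c("in12", "in12"), hours_after = c(1, 14 * 24 - 2))
  res <- classify_residency(det, bh_dep, bh_towers)
  expect_true(res$resident)
  expect_identical(res$min_residency_days, 14L)

  # only the release night: not resident
  det1 <- bh_track("in12", hours_after = 1)
  expect_false(classify_residency(det1, bh_dep, bh_towers)$resident)

  # a 30 km tower is outside the 12 km local radius
  det30 <- bh_track(c("out30", "out30"), hours_after = c(1, 25))
  res30 <- classify_residency(det30, bh_dep, bh_towers)
  expect_false(res30$resident)
  expect_true(is.na(res30$min_residency_days))

  # the radius is strict: a tower at exactly 12 km is not local
  detat <- bh_track(c("at12", "at12"), hours_after = c(1, 25))
  expect_false(classify_residency(detat, bh_dep, bh_towers)$resident)
  detin <- bh_track(c("in12", "in12"), hours_after = c(1, 25))
  expect_true(classify_residency(detin, bh_dep, bh_towers)$resident)
})

test_that("travel bearing points from release to the last tower", {
  tw <- rbind(fx_tower_at("east", 90, 60), fx_tower_at("south", 180, 60))
  det <- fx_detections("t1", bh_dep$release_time + c(1, 2) * 3600,
                       c("east", "south"))
  expect_equal(travel_bearing(det, bh_dep, tw), 180, tolerance = 0.5)
  det2 <- fx_detections("t1", bh_dep$release_time + c(1, 2) * 3600,
                        c("south", "east"))
  expect_equal(travel_bearing(det2, bh_dep, tw), 90, tolerance = 0.5)
})

test_that("cohort summary aggregates counts, bearings, and residency", {
  s <- data.frame(
    tag_id = sprintf("t%d", 1:6),
    detected = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    resident = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    migrant = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    long_distance_return = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    bearing_deg = c(NA, NA, 10, 350, NA, NA),
    min_residency_days = c(2L, 15L, 32L, NA, NA, NA),
    last_tower_id = "x",
    last_detection_time = utc("2021-09-20 02:00:00"),
    stringsAsFactors = FALSE
  )
  co <- summarize_cohort(s)
  expect_identical(co$n_tagged, 6L)
  expect_identical(co$n_detected, 5L)
  expect_identical(co$n_migrant, 2L)
  expect_identical(co$n_both, 1L)
  expect_identical(co$n_return, 1L)
  expect_equal(co$mean_bearing_deg, 0, tolerance = 1e-10)
  expect_equal(co$min_bearing_deg, 10)
  expect_equal(co$max_bearing_deg, 350)
  expect_equal(co$residency_mean_days, mean(c(2, 15, 32)))
  # linear-interpolation quantiles of {2, 15, 32}, frozen by hand:
  # h05 = 1.1 -> 2 + 0.1 * 13 = 3.3; h95 = 2.9 -> 15 + 0.9 * 17 = 30.3
  expect_equal(co$residency_q05, 3.3)
  expect_equal(co$residency_q95, 30.3)

  s$bearing_deg <- c(NA, NA, 90, 270, NA, NA)
  co2 <- summarize_cohort(s)
  expect_true(is.na(co2$mean_bearing_deg))
  expect_true(co2$bearing_undefined)
})

test_that("classification is invariant to detection order shuffles", {
  cfg <- scenario_config(seed = 31, n_bats = c(resident = 1L, migrant = 1L,
                                               crosser = 1L, returner = 1L))
  sc <- simulate_scenario(cfg)
  set.seed(99)
  for (tag in sc$deployments$tag_id) {
    dep <- sc$deployments[sc$deployments$tag_id == tag, , drop = FALSE]
    det <- clean_track(sc$detections[sc$detections$tag_id == tag, ,
                                     drop = FALSE], dep, sc$towers)
    shuffled <- det[sample.int(nrow(det)), , drop = FALSE]
    shuffled <- shuffled[order(shuffled$timestamp), , drop = FALSE]
    expect_identical(classify_migration(shuffled, sc$towers),
                     classify_migration(det, sc$towers))
    r1 <- classify_residency(det, dep, sc$towers)
    r2 <- classify_residency(shuffled, dep, sc$towers)
    expect_identical(r1, r2)
    # residency never exceeds the whole-day span of the track
    if (!is.na(r1$min_residency_days)) {
      expect_lte(r1$min_residency_days,
                 as.integer(as.Date(max(det$timestamp)) -
                              as.Date(dep$release_time)))
    }
  }
})
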