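# Seeded synthetic study generator. Emulates the field setting the pipeline
# was built for: a mid-Atlantic coastal tower network with receivers on both
# shores of two bays, hourly coastal weather with diurnal and frontal
# structure, and tagged bats of four behavioural archetypes (resident,
# migrant, bay-crosser, long-distance-returner) whose trajectories produce
# Motus-style detection tables with ground-truth labels.
#
# Every stage reseeds from (config$seed + a fixed stage offset), so weather,
# positions, and detections are each independently reproducible.

.SEED_TOWERS <- 11L
.SEED_WEATHER <- 23L
.SEED_BATS <- 37L
.SEED_DETECT <- 53L

#' Scenario configuration for the synthetic study
#'
#' Builds the default simulation scenario: a fall tagging season on the
#' Delmarva peninsula, receiver towers with a 12 km detection range on both
#' sides of two bays, 15-30 day tag lives, and archetype counts at a scale a
#' single desktop run can analyse end to end. Any field can be overridden
#' via `...`.
#'
#' @param seed Integer root seed; all stage seeds derive from it.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `scenario_config`. Key fields:
#'   `detection_range_km` (12) and `full_detect_km` (6, range of certain
#'   detection); `n_bats` named counts per archetype; `study_start`,
#'   `study_end`; `crossing_beta` the true hour-level logistic coefficients
#'   of a bay crossing (intercept, hours_since_sunset, wind_speed,
#'   temperature); `hmm_truth` the two-state activity truth (emission means
#'   and SDs of the hourly signal-variability metric, and per-origin-state
#'   transition coefficients (alpha, beta_sin, beta_cos) on the logit of
#'   moving to / staying in the active state); signal-model constants
#'   (`signal_s0`, `signal_k`, per-state noise SDs).
#' @export
scenario_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    detection_range_km = 12,
    full_detect_km = 6,
    n_bats = c(resident = 12L, migrant = 10L, crosser = 10L, returner = 4L),
    study_start = as.Date("2021-08-15"),
    study_end = as.Date("2021-10-15"),
    tag_life_range = c(15, 30),
    crossing_beta = c(intercept = -4.6, hours_since_sunset = -0.31,
                      wind_speed = -0.31, temperature = 0.12),
    crossing_horizon_days = 40,
    hmm_truth = list(
      mu_rest = 0.3, sd_rest = 0.15, mu_active = 1.0, sd_active = 0.35,
      trans_rest = c(-2.0, 3.0, 0.0),    # logit P(active next | rest)
      trans_active = c(1.0, 1.5, 0.0)    # logit P(active next | active)
    ),
    signal_s0 = -40, signal_k = 25,
    noise_sd_rest = 2.5, noise_sd_active = 6,
    mean_run_length = 6,
    noise_run_rate = 0.002,   # spurious short runs per tower-hour
    far_noise_rate = 0.0005,  # spurious detections at the distant tower
    resident_radius_km = 10,
    migrant_heading_mean = 230, migrant_heading_sd = 12,
    migrant_step_km = c(mean = 60, sd = 15),
    activity_intercept = -1.5, activity_temp_slope = 0.18
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$detection_range_km <= 0) stop("detection_range_km must be > 0", call. = FALSE)
  if (any(cfg$n_bats < 0)) stop("archetype counts must be >= 0", call. = FALSE)
  if (cfg$study_end <= cfg$study_start) stop("study_end must follow study_start", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

#' Synthetic tower network
#'
#' Towers on both shores of two labelled water bodies ("chesapeake",
#' "delaware"), a southwest migration corridor, local towers at the two
#' release sites, and one distant continental tower that only ever logs
#' noise (to exercise the implausibility filter).
#'
#' @param config A [scenario_config()].
#' @return A towers data.frame (`tower_id, lat, lon, water_body, side`), one
#'   row per tower-waterbody adjacency, with attribute `release_sites`.
#' @export
simulate_towers <- function(config) {
  es <- c(37.20, -75.93)   # Eastern Shore release site, east of the bay mouth
  nj <- c(39.05, -74.85)   # southern New Jersey release site
  coords <- list(
    ches_e1 = c(37.15, -75.95), ches_e2 = c(37.25, -75.91),
    ches_w1 = c(37.05, -76.35), ches_w2 = c(37.00, -76.33),
    del_e1 = c(39.00, -74.90), del_w1 = c(38.80, -75.25),
    home_es = es, home_nj = nj,
    far_west = c(36.5, -119.5)
  )
  # Migration-corridor fan: rings of towers every 35 km out to ~315 km from
  # the Eastern Shore site, spanning bearings 200-260 deg, spaced so that a
  # bat flying through a ring passes within detection range of some tower.
  k <- 0
  for (r in seq(35, 315, by = 35)) {
    dtheta <- max(min(30, 22 / r * 180 / pi), 3)
    for (th in seq(200, 260, by = dtheta)) {
      k <- k + 1
      p <- destination_point(es[1], es[2], th, r)
      coords[[sprintf("cor_%03d", k)]] <- c(p$lat, p$lon)
    }
  }
  t0 <- data.frame(
    tower_id = names(coords),
    lat = vapply(coords, `[`, 0.0, 1),
    lon = vapply(coords, `[`, 0.0, 2),
    water_body = NA_character_, side = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(t0) <- NULL
  t0$water_body[t0$tower_id %in% c("ches_e1", "ches_e2", "ches_w1", "ches_w2")] <- "chesapeake"
  t0$side[t0$tower_id %in% c("ches_e1", "ches_e2")] <- "east"
  t0$side[t0$tower_id %in% c("ches_w1", "ches_w2")] <- "west"
  t0$water_body[t0$tower_id %in% c("del_e1", "del_w1")] <- "delaware"
  t0$side[t0$tower_id == "del_e1"] <- "east"
  t0$side[t0$tower_id == "del_w1"] <- "west"
  attr(t0, "release_sites") <- data.frame(
    site_id = c("east_shore", "new_jersey"),
    lat = c(es[1], nj[1]), lon = c(es[2], nj[2]),
    stringsAsFactors = FALSE
  )
  t0
}

#' Synthetic hourly weather
#'
#' One station per release site (collocated, so no interpolation is needed
#' downstream). Temperature is a seasonal linear decline plus a diurnal
#' sinusoid plus AR(1) noise; wind speed is an exponentiated AR(1) (always
#' positive); wind direction is a wrapped random walk; pressure is AR(1)
#' with occasional frontal step changes; precipitation comes in sparse
#' bursts; visibility is 16 km minus a precipitation-coupled reduction,
#' clamped to [0, 16].
#'
#' @param config A [scenario_config()].
#' @param stations Optional data.frame (`station_id, lat, lon`); defaults to
#'   the release sites of [simulate_towers()].
#' @return A weather data.frame (see [read_weather()]); hourly from three
#'   days before `study_start` through one day past `study_end`.
#' @export
simulate_weather <- function(config, stations = NULL) {
  if (is.null(stations)) {
    rs <- attr(simulate_towers(config), "release_sites")
    stations <- data.frame(station_id = rs$site_id, lat = rs$lat, lon = rs$lon,
                           stringsAsFactors = FALSE)
  }
  start <- as.POSIXct(paste(config$study_start - 3, "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(config$study_end + 1, "23:00:00"), tz = "UTC")
  if (end <= start) stop("study end precedes start", call. = FALSE)
  hours <- seq(start, end, by = "hour")
  nh <- length(hours)
  set.seed(config$seed + .SEED_WEATHER)
  out <- vector("list", nrow(stations))
  for (s in seq_len(nrow(stations))) {
    lon <- stations$lon[s]
    day_frac <- as.numeric(difftime(hours, start, units = "days"))
    season <- 24 - 12 * day_frac / max(day_frac)          # ~24 C down to ~12 C
    hloc <- (as.numeric(hours) / 3600 + lon / 15) %% 24   # local solar hour
    diurnal <- 4 * cos(2 * pi * (hloc - 15) / 24)         # warmest ~15:00 local
    ar <- stats::filter(stats::rnorm(nh, 0, 1.0 * sqrt(1 - 0.8^2)), 0.8,
                        method = "recursive")
    temperature <- season + diurnal + as.numeric(ar)
    lw <- stats::filter(stats::rnorm(nh, 0, 0.35), 0.9, method = "recursive")
    wind_speed <- exp(0.8 + as.numeric(lw))
    wind_dir <- (cumsum(stats::rnorm(nh, 0, 25)) + 200) %% 360
    fronts <- stats::rbinom(nh, 1, 1 / 96) *
      stats::rnorm(nh, 0, 0.8)
    par <- stats::filter(stats::rnorm(nh, 0, 0.05) + fronts, 0.98,
                         method = "recursive")
    pressure <- 101.3 + as.numeric(par)
    wet <- stats::rbinom(nh, 1, 0.05)
    # extend bursts: a wet hour stays wet with probability 0.6
    for (i in 2:nh) if (wet[i - 1] == 1 && stats::runif(1) < 0.6) wet[i] <- 1
    precipitation <- wet * stats::rexp(nh, rate = 5)
    visibility <- pmin(pmax(16 - 40 * precipitation - abs(stats::rnorm(nh, 0, 0.4)),
                            0), 16)
    out[[s]] <- data.frame(
      station_id = stations$station_id[s], timestamp = hours,
      temperature = temperature, wind_speed = wind_speed,
      wind_dir = wind_dir, pressure = pressure,
      precipitation = precipitation, visibility = visibility,
      stringsAsFactors = FALSE
    )
  }
  w <- do.call(rbind, out)
  attr(w, "stations") <- stations
  w
}

# Nearest station id for a point.
.nearest_station <- function(lat, lon, stations) {
  d <- haversine_km(lat, lon, stations$lat, stations$lon)
  stations$station_id[which.min(d)]
}

# Weather row lookup at a whole hour; errors when missing.
.weather_at <- function(weather, station_id, hour) {
  i <- which(weather$station_id == station_id & weather$timestamp == hour)
  if (length(i) == 0) {
    stop(sprintf("missing weather for station %s at %s", station_id,
                 .format_utc(hour)), call. = FALSE)
  }
  weather[i[1], , drop = FALSE]
}

#' Synthetic bat trajectories with ground-truth labels
#'
#' Hourly ground-truth positions for each archetype. Residents random-walk
#' within 10 km of release, roosting by day, with a nightly per-hour
#' probability of being active that falls with temperature. Migrants hold
#' residency a few nights then take nightly steps along a heading drawn near
#' 230 degrees. Crossers are residents whose probability of initiating a
#' same-night bay transit in any night hour follows
#' `plogis(crossing_beta . (1, hours_since_sunset, wind_speed, temperature))`
#' -- the recovery target for the selection-model stage. Returners make one
#' >50 km excursion and come back.
#'
#' @param config A [scenario_config()].
#' @param towers Towers data.frame from [simulate_towers()] (its
#'   `release_sites` attribute is used).
#' @param weather Weather data.frame from [simulate_weather()].
#' @return A list with `positions` (tag_id, timestamp, lat, lon, state),
#'   `deployments` (see [read_deployments()]), and `truth` (a list with
#'   per-tag `archetype`, `true_crossing_nights`, and an hourly-state
#'   data.frame).
#' @export
simulate_bats <- function(config, towers, weather) {
  if (sum(config$n_bats) == 0) stop("all archetype counts are zero", call. = FALSE)
  stations <- attr(weather, "stations")
  sites <- attr(towers, "release_sites")
  if (is.null(sites)) stop("towers lack release_sites attribute", call. = FALSE)
  set.seed(config$seed + .SEED_BATS)

  archetypes <- rep(names(config$n_bats), times = config$n_bats)
  n <- length(archetypes)
  tag_ids <- sprintf("tag%03d", seq_len(n))

  # Mobile archetypes are released on the Eastern Shore (east side of the
  # Chesapeake, inside the corridor fan); residents split between sites.
  site_idx <- ifelse(archetypes == "resident",
                     1L + (seq_len(n) %% nrow(sites)), 1L)
  rel_lat <- sites$lat[site_idx] + stats::rnorm(n, 0, 0.01)
  rel_lon <- sites$lon[site_idx] + stats::rnorm(n, 0, 0.01)
  rel_date <- config$study_start +
    sample.int(14, n, replace = TRUE) - 1
  tag_life <- stats::runif(n, config$tag_life_range[1], config$tag_life_range[2])
  release_time <- vector("list", n)
  deployments <- data.frame(
    tag_id = tag_ids, species = "LABO",
    sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.35, 0.65)),
    age = sample(c("adult", "juvenile"), n, replace = TRUE, prob = c(0.65, 0.35)),
    release_time = as.POSIXct(NA, tz = "UTC"),
    release_lat = rel_lat, release_lon = rel_lon,
    tag_life_days = tag_life, stringsAsFactors = FALSE
  )
  weather_end <- max(weather$timestamp)

  west_target <- towers[towers$tower_id == "ches_w1", ]
  positions <- vector("list", n)
  truth <- vector("list", n)
  names(truth) <- tag_ids

  for (b in seq_len(n)) {
    arch <- archetypes[b]
    ss <- sunset_utc(rel_date[b], rel_lat[b], rel_lon[b])
    rel_t <- .floor_hour(ss + stats::runif(1, 0.5, 2) * 3600)
    deployments$release_time[b] <- rel_t
    end_t <- min(rel_t + tag_life[b] * 86400, weather_end)
    hours <- seq(rel_t, .floor_hour(end_t), by = "hour")
    nh <- length(hours)
    stn <- .nearest_station(rel_lat[b], rel_lon[b], stations)
    widx <- match(paste(stn, as.numeric(hours)),
                  paste(weather$station_id, as.numeric(weather$timestamp)))
    temp_h <- weather$temperature[widx]
    wind_h <- weather$wind_speed[widx]
    night <- is_night(hours, rel_lat[b], rel_lon[b])
    hss <- hours_since_sunset(hours, rel_lat[b], rel_lon[b])

    # hourly rest/active truth: roost (rest) by day; at night a two-state
    # Markov chain whose stationary probability of activity rises with
    # temperature (rest comes in multi-hour torpor-like bouts)
    p_stat <- stats::plogis(config$activity_intercept +
                              config$activity_temp_slope * temp_h)
    kappa <- 0.35  # per-hour mixing rate of the activity chain
    state <- rep("rest", nh)
    prev_night <- FALSE
    for (i in seq_len(nh)) {
      if (!night[i]) {
        prev_night <- FALSE
        next
      }
      p_act <- if (!prev_night) {
        p_stat[i]  # dusk: draw from the stationary law
      } else if (state[i - 1] == "active") {
        1 - (1 - p_stat[i]) * kappa
      } else {
        p_stat[i] * kappa
      }
      state[i] <- if (stats::runif(1) < p_act) "active" else "rest"
      prev_night <- TRUE
    }

    lat <- rep(rel_lat[b], nh); lon <- rep(rel_lon[b], nh)
    cross_nights <- as.Date(character(0))

    jitter_local <- function(i) {
      # active-hour foraging positions within the resident radius
      ang <- stats::runif(length(i), 0, 360)
      dist <- stats::runif(length(i), 0, min(3, config$resident_radius_km))
      p <- destination_point(rel_lat[b], rel_lon[b], ang, dist)
      lat[i] <<- p$lat; lon[i] <<- p$lon
    }

    if (arch %in% c("resident", "crosser", "returner")) {
      jitter_local(which(state == "active"))
    }

    if (arch == "crosser") {
      nid <- night_id(hours, rel_lat[b], rel_lon[b])
      horizon <- rel_t + config$crossing_horizon_days * 86400
      crossed_tonight <- as.Date(character(0))
      i <- 1
      while (i <= nh) {
        if (night[i] && hours[i] <= horizon && !(nid[i] %in% crossed_tonight) &&
            hss[i] <= 10) {
          x <- c(1, hss[i], wind_h[i], temp_h[i])
          p_cross <- stats::plogis(sum(config$crossing_beta * x))
          if (!is.na(p_cross) && stats::runif(1) < p_cross) {
            crossed_tonight <- c(crossed_tonight, nid[i])
            cross_nights <- c(cross_nights, nid[i])
            # transit: depart now, arrive on the west shore two hours later,
            # linger three hours, return before dawn when time allows
            path_hours <- i:min(i + 7, nh)
            wp <- c(west_target$lat, west_target$lon)
            stops <- list(
              c(lat[i], lon[i]),
              c((lat[i] + wp[1]) / 2, (lon[i] + wp[2]) / 2),
              wp, wp, wp,
              c((lat[i] + wp[1]) / 2, (lon[i] + wp[2]) / 2),
              c(rel_lat[b], rel_lon[b]), c(rel_lat[b], rel_lon[b])
            )
            for (k in seq_along(path_hours)) {
              lat[path_hours[k]] <- stops[[k]][1]
              lon[path_hours[k]] <- stops[[k]][2]
              state[path_hours[k]] <- ifelse(k <= 6, "active", state[path_hours[k]])
            }
            i <- i + 8
            next
          }
        }
        i <- i + 1
      }
    } else if (arch == "migrant") {
      heading <- stats::rnorm(1, config$migrant_heading_mean,
                              config$migrant_heading_sd)
      heading <- max(min(heading, config$migrant_heading_mean + 25),
                     config$migrant_heading_mean - 25)
      depart_night <- sample.int(5, 1)
      nid <- night_id(hours, rel_lat[b], rel_lon[b])
      nights <- sort(unique(nid[night]))
      cur <- c(rel_lat[b], rel_lon[b])
      total <- 0
      for (nn in nights[-seq_len(min(depart_night, length(nights)))]) {
        if (total > 320) break
        step <- max(stats::rnorm(1, config$migrant_step_km["mean"],
                                 config$migrant_step_km["sd"]), 20)
        idx <- which(nid == nn & night)
        if (!length(idx)) next
        for (k in seq_along(idx)) {
          frac <- k / length(idx)
          p <- destination_point(cur[1], cur[2], heading, step * frac)
          lat[idx[k]] <- p$lat; lon[idx[k]] <- p$lon
          state[idx[k]] <- "active"
        }
        p <- destination_point(cur[1], cur[2], heading, step)
        cur <- c(p$lat, p$lon); total <- total + step
        # daytime roost at the stopover until the next migration night
        after <- which(hours > max(hours[idx]))
        lat[after] <- cur[1]; lon[after] <- cur[2]
      }
      attr(cross_nights, "heading") <- heading
    } else if (arch == "returner") {
      nid <- night_id(hours, rel_lat[b], rel_lon[b])
      nights <- sort(unique(nid[night]))
      if (length(nights) >= 8) {
        out_heading <- stats::runif(1, 210, 250)
        away <- destination_point(rel_lat[b], rel_lon[b], out_heading, 70)
        plan <- list(away, away, away, away)  # four nights away
        excursion_nights <- nights[4:7]
        for (j in seq_along(excursion_nights)) {
          idx <- which(nid == excursion_nights[j])
          lat[idx] <- plan[[j]]$lat; lon[idx] <- plan[[j]]$lon
        }
        # also hold the away position through the intervening days
        span <- which(hours >= min(hours[nid == excursion_nights[1]]) &
                        hours <= max(hours[nid == excursion_nights[4]]))
        lat[span] <- away$lat; lon[span] <- away$lon
      }
    }

    positions[[b]] <- data.frame(
      tag_id = tag_ids[b], timestamp = hours, lat = lat, lon = lon,
      state = state, stringsAsFactors = FALSE
    )
    truth[[b]] <- list(
      tag_id = tag_ids[b], archetype = arch,
      true_crossing_nights = cross_nights,
      true_hourly_state = data.frame(timestamp = hours, state = state,
                                     stringsAsFactors = FALSE),
      heading = if (arch == "migrant") attr(cross_nights, "heading") else NA_real_
    )
  }
  list(positions = do.call(rbind, positions), deployments = deployments,
       truth = truth)
}

#' Synthetic detection tables from ground-truth positions
#'
#' A position within `full_detect_km` of a tower is always detected; between
#' that and `detection_range_km` the detection probability falls linearly to
#' zero. A detection yields a reception run of several pulses within the
#' hour; signal strength is `s0 - k*log(d_km + 1)` plus Gaussian noise whose
#' SD is larger while the bat's true state is "active" (this within-hour
#' variability is what the activity HMM later recovers). Sparse spurious
#' short runs (run length 1-3) and rare hits at the distant noise tower
#' exercise the cleaning filters.
#'
#' @param positions Positions data.frame from [simulate_bats()].
#' @param towers Towers data.frame.
#' @param config A [scenario_config()].
#' @return A detections data.frame (see [read_detections()]).
#' @export
simulate_detections <- function(positions, towers, config) {
  set.seed(config$seed + .SEED_DETECT)
  tw <- towers[!duplicated(towers$tower_id), ]
  rows <- vector("list", 2000); nr <- 0
  add <- function(df) { nr <<- nr + 1; rows[[nr]] <<- df }
  for (ti in seq_len(nrow(tw))) {
    d <- haversine_km(positions$lat, positions$lon, tw$lat[ti], tw$lon[ti])
    p_det <- ifelse(d <= config$full_detect_km, 1,
                    pmax(0, (config$detection_range_km - d) /
                           (config$detection_range_km - config$full_detect_km)))
    hit <- which(stats::runif(length(d)) < p_det)
    if (tw$tower_id[ti] == "far_west") {
      # only noise at the continental tower
      hit <- which(stats::runif(nrow(positions)) < config$far_noise_rate)
      if (!length(hit)) next
      add(data.frame(
        tag_id = positions$tag_id[hit],
        timestamp = positions$timestamp[hit] + round(stats::runif(length(hit), 0, 3599)),
        tower_id = tw$tower_id[ti],
        antenna_id = "a1",
        signal_strength = stats::rnorm(length(hit), -95, 3),
        run_length = sample(1:3, length(hit), replace = TRUE),
        stringsAsFactors = FALSE
      ))
      next
    }
    if (!length(hit)) next
    run_len <- 2L + stats::rpois(length(hit), config$mean_run_length - 2)
    active <- positions$state[hit] == "active"
    n_pulse <- pmin(run_len, 8L)
    base_sig <- config$signal_s0 - config$signal_k * log(d[hit] + 1)
    ant <- sample(c("a1", "a2"), length(hit), replace = TRUE)
    reps <- rep(seq_along(hit), n_pulse)
    offs <- unlist(lapply(n_pulse, function(k) sort(stats::runif(k, 0, 3599))))
    sd_vec <- ifelse(active, config$noise_sd_active, config$noise_sd_rest)
    add(data.frame(
      tag_id = positions$tag_id[hit][reps],
      timestamp = positions$timestamp[hit][reps] + round(offs),
      tower_id = tw$tower_id[ti],
      antenna_id = ant[reps],
      signal_strength = base_sig[reps] +
        ifelse(ant[reps] == "a2", 3, 0) +  # antenna gain offset
        stats::rnorm(length(reps), 0, sd_vec[reps]),
      run_length = run_len[reps],
      stringsAsFactors = FALSE
    ))
    # sparse spurious short runs at this tower
    n_noise <- stats::rpois(1, config$noise_run_rate * nrow(positions))
    if (n_noise > 0) {
      j <- sample.int(nrow(positions), n_noise)
      add(data.frame(
        tag_id = positions$tag_id[j],
        timestamp = positions$timestamp[j] + round(stats::runif(n_noise, 0, 3599)),
        tower_id = tw$tower_id[ti],
        antenna_id = "a1",
        signal_strength = stats::rnorm(n_noise, -90, 4),
        run_length = sample(1:3, n_noise, replace = TRUE),
        stringsAsFactors = FALSE
      ))
    }
  }
  if (nr == 0) {
    return(data.frame(tag_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      tower_id = character(0), antenna_id = character(0),
                      signal_strength = numeric(0), run_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  det <- do.call(rbind, rows[seq_len(nr)])
  det <- det[order(det$tag_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Run the full synthetic scenario
#'
#' Towers, weather, trajectories, detections, and truth labels in one call.
#'
#' @param config A [scenario_config()].
#' @return A list with `towers`, `weather`, `deployments`, `positions`,
#'   `detections`, and `truth`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  towers <- simulate_towers(config)
  weather <- simulate_weather(config)
  bats <- simulate_bats(config, towers, weather)
  detections <- simulate_detections(bats$positions, towers, config)
  list(towers = towers, weather = weather, deployments = bats$deployments,
       positions = bats$positions, detections = detections, truth = bats$truth)
}

#' Simulate hourly crossing decisions from the true selection model
#'
#' A lighter-weight generator used for parameter-recovery experiments on the
#' over-water selection model: for each simulated individual, every whole
#' hour of its post-release horizon is an independent Bernoulli trial with
#' success probability `plogis(crossing_beta . x)`; successful hours are
#' the "used" instances. No explicit night gate or per-night cap is
#' applied -- the hours-since-sunset coefficient itself makes daytime
#' crossings vanishingly rare, and a bat that crosses and returns within a
#' night legitimately contributes two instances -- which keeps the
#' generating law exactly the logistic model the selection stage fits.
#'
#' @param config A [scenario_config()] (fields `crossing_beta`,
#'   `crossing_horizon_days`).
#' @param weather Weather data.frame from [simulate_weather()].
#' @param n_tags Number of simulated individuals.
#' @param seed Seed for this experiment.
#' @return A list with `used` (data.frame tag_id, timestamp),
#'   `deployments`, and the reference `station`/`lat`/`lon` used for
#'   covariates.
#' @export
simulate_crossing_events <- function(config, weather, n_tags = 30, seed = 1L) {
  set.seed(seed)
  stations <- attr(weather, "stations")
  stn <- stations$station_id[1]
  lat <- stations$lat[1]; lon <- stations$lon[1]
  wsub <- weather[weather$station_id == stn, ]
  hss_all <- hours_since_sunset(wsub$timestamp, lat, lon)
  used <- vector("list", n_tags)
  rel <- as.POSIXct(character(0), tz = "UTC")
  for (b in seq_len(n_tags)) {
    rel_t <- as.POSIXct(paste(config$study_start + sample.int(10, 1) - 1,
                              "22:00:00"), tz = "UTC")
    rel <- c(rel, rel_t)
    win <- wsub$timestamp >= rel_t &
      wsub$timestamp <= rel_t + config$crossing_horizon_days * 86400
    idx <- which(win)
    eta <- config$crossing_beta["intercept"] +
      config$crossing_beta["hours_since_sunset"] * hss_all[idx] +
      config$crossing_beta["wind_speed"] * wsub$wind_speed[idx] +
      config$crossing_beta["temperature"] * wsub$temperature[idx]
    hitrows <- idx[stats::runif(length(idx)) < stats::plogis(eta)]
    if (length(hitrows)) {
      used[[b]] <- data.frame(tag_id = sprintf("xtag%03d", b),
                              timestamp = wsub$timestamp[hitrows],
                              stringsAsFactors = FALSE)
    }
  }
  deployments <- data.frame(
    tag_id = sprintf("xtag%03d", seq_len(n_tags)),
    species = "LABO", sex = "unknown", age = "unknown",
    release_time = rel, release_lat = lat, release_lon = lon,
    tag_life_days = config$crossing_horizon_days + 1,
    stringsAsFactors = FALSE
  )
  list(used = do.call(rbind, used), deployments = deployments,
       station = stn, lat = lat, lon = lon)
}

#' Simulate an hourly activity series from known two-state truth
#'
#' Generates a state sequence from the covariate-dependent transition model
#' in `config$hmm_truth` (sine/cosine of hours since sunset on a 24 h
#' period) and Gaussian emissions, as a ground-truth fixture for HMM
#' parameter-recovery experiments.
#'
#' @param config A [scenario_config()].
#' @param n_hours Series length in hours.
#' @param seed Seed for this experiment.
#' @param lat,lon Site coordinates for the sunset clock.
#' @param start First hour (POSIXct UTC).
#' @return A list with `series` (an activity-series data.frame with columns
#'   `tag_id, hour, value, hss_sin, hss_cos, segment_id`) and `states`
#'   (character vector of true states).
#' @export
simulate_hmm_series <- function(config, n_hours = 600, seed = 1L,
                                lat = 37.45, lon = -75.85,
                                start = as.POSIXct("2021-09-01 00:00:00",
                                                   tz = "UTC")) {
  set.seed(seed)
  tr <- config$hmm_truth
  hours <- seq(start, by = "hour", length.out = n_hours)
  hss <- hours_since_sunset(hours, lat, lon)
  cyc <- cyclical_hour(hss %% 24)
  states <- character(n_hours)
  states[1] <- "rest"
  for (i in 2:n_hours) {
    co <- if (states[i - 1] == "rest") tr$trans_rest else tr$trans_active
    p_act <- stats::plogis(co[1] + co[2] * cyc$sin[i] + co[3] * cyc$cos[i])
    states[i] <- if (stats::runif(1) < p_act) "active" else "rest"
  }
  mu <- ifelse(states == "active", tr$mu_active, tr$mu_rest)
  sd <- ifelse(states == "active", tr$sd_active, tr$sd_rest)
  value <- pmax(stats::rnorm(n_hours, mu, sd), 0)
  series <- data.frame(tag_id = "sim", hour = hours, value = value,
                       hss_sin = cyc$sin, hss_cos = cyc$cos,
                       segment_id = 1L, stringsAsFactors = FALSE)
  list(series = series, states = states)
}
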