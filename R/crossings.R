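# Over-water crossing detection and the use-availability table. A crossing
# is a same-night pair of detections on opposite labelled shores of a water
# body; its time is the departure/arrival midpoint rounded to the nearest
# whole hour (half-up). Availability is temporal: random hours in each
# contributing tag's first `horizon_days` post-release.

#' Detect same-night over-water crossings
#'
#' For each tag, water body, and night: whenever the time-ordered sequence
#' of shore-side labels switches, one crossing event is emitted, with
#' departure = the last detection on the origin side and arrival = the first
#' detection on the opposite side. A return across the same water body in
#' the same night yields a second event. Towers bordering a water body but
#' lacking a side label are ignored for that body with a warning.
#'
#' @param detections Cleaned detections data.frame (all tags).
#' @param towers Towers data.frame with `water_body`/`side` labels.
#' @param deployments Deployments data.frame (release coordinates give the
#'   night clock; towers are all within tens of km of the release sites).
#' @return A data.frame with columns `tag_id, water_body, night_id,
#'   departure_time, arrival_time, departure_tower, arrival_tower,
#'   midpoint_hour`.
#' @export
detect_crossings <- function(detections, towers, deployments) {
  adj <- towers[!is.na(towers$water_body), , drop = FALSE]
  unlabeled <- adj[is.na(adj$side), , drop = FALSE]
  if (nrow(unlabeled)) {
    warning("ignoring tower(s) without a side label: ",
            paste(unique(unlabeled$tower_id), collapse = ", "))
    adj <- adj[!is.na(adj$side), , drop = FALSE]
  }
  empty <- data.frame(tag_id = character(0), water_body = character(0),
                      night_id = as.Date(character(0)),
                      departure_time = as.POSIXct(character(0), tz = "UTC"),
                      arrival_time = as.POSIXct(character(0), tz = "UTC"),
                      departure_tower = character(0),
                      arrival_tower = character(0),
                      midpoint_hour = as.POSIXct(character(0), tz = "UTC"),
                      stringsAsFactors = FALSE)
  if (nrow(adj) == 0 || nrow(detections) == 0) return(empty)
  out <- list(empty)
  for (wb in unique(adj$water_body)) {
    wt <- adj[adj$water_body == wb, ]
    if (length(unique(wt$side)) < 2) next
    det <- detections[detections$tower_id %in% wt$tower_id, , drop = FALSE]
    if (nrow(det) == 0) next
    det$side <- wt$side[match(det$tower_id, wt$tower_id)]
    for (tag in unique(det$tag_id)) {
      dep <- deployments[deployments$tag_id == tag, , drop = FALSE]
      if (nrow(dep) == 0) next
      dt <- det[det$tag_id == tag, , drop = FALSE]
      dt <- dt[order(dt$timestamp), , drop = FALSE]
      dt$night <- night_id(dt$timestamp, dep$release_lat, dep$release_lon)
      for (nn in as.list(unique(dt$night))) {  # as.list keeps the Date class
        dn <- dt[dt$night == nn, , drop = FALSE]
        if (length(unique(dn$side)) < 2) next
        switches <- which(dn$side[-1] != dn$side[-nrow(dn)])
        for (s in switches) {
          out[[length(out) + 1]] <- data.frame(
            tag_id = tag, water_body = wb, night_id = nn,
            departure_time = dn$timestamp[s],
            arrival_time = dn$timestamp[s + 1],
            departure_tower = dn$tower_id[s],
            arrival_tower = dn$tower_id[s + 1],
            midpoint_hour = .round_hour_half_up(
              dn$timestamp[s] + as.numeric(dn$timestamp[s + 1] -
                                             dn$timestamp[s], units = "secs") / 2),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sample available (background) hours for the use-availability design
#'
#' For each tag contributing used instances, draws `ratio` times that tag's
#' used count of whole hours, uniformly over `[release, release +
#' horizon_days]`, excluding hours equal to any of the tag's used midpoints.
#'
#' @param events Crossing events from [detect_crossings()] (or any
#'   data.frame with `tag_id` and `midpoint_hour`).
#' @param deployments Deployments data.frame.
#' @param ratio Available:used ratio (default 10).
#' @param horizon_days Post-release availability window in days (default 40).
#' @param seed Integer seed for the draw.
#' @param pooled With the default `FALSE`, each contributing tag draws
#'   `ratio` times its own used count (availability proportional to use).
#'   With `TRUE`, the total `ratio * n_used` draws are spread evenly over
#'   the contributing tags' windows regardless of how many crossings each
#'   made.
#' @return A data.frame `tag_id, timestamp` with exactly
#'   `ratio * nrow(events)` rows (empty when there are no events).
#' @export
sample_available <- function(events, deployments, ratio = 10,
                             horizon_days = 40, seed = 1L, pooled = FALSE) {
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  if (is.null(events) || nrow(events) == 0) {
    return(data.frame(tag_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  tags <- unique(events$tag_id)
  n_draw <- vapply(tags, function(tag) {
    as.integer(ratio * sum(events$tag_id == tag))
  }, 0L)
  if (pooled) {
    total <- sum(n_draw)
    n_draw <- rep(total %/% length(tags), length(tags))
    extra <- total - sum(n_draw)
    if (extra > 0) n_draw[seq_len(extra)] <- n_draw[seq_len(extra)] + 1L
    names(n_draw) <- tags
  }
  out <- list()
  for (tag in tags) {
    used <- events$midpoint_hour[events$tag_id == tag]
    dep <- deployments[deployments$tag_id == tag, , drop = FALSE]
    if (nrow(dep) == 0) stop("no deployment for tag ", tag, call. = FALSE)
    grid <- seq(.floor_hour(dep$release_time) + 3600,
                .floor_hour(dep$release_time + horizon_days * 86400),
                by = "hour")
    grid <- grid[!(as.numeric(grid) %in% as.numeric(used))]
    draw <- grid[sample.int(length(grid), n_draw[[tag]], replace = TRUE)]
    out[[tag]] <- data.frame(tag_id = tag, timestamp = draw,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the use-availability table with atmospheric covariates
#'
#' Stacks used midpoints (`used = 1`) and available hours (`used = 0`) and
#' attaches, from the nearest weather station to each tag's release site:
#' hours since sunset; instantaneous wind speed, temperature, precipitation,
#' visibility, and pressure; the zonal/meridional wind components
#' (`wind_x = speed * sin(dir)`, `wind_y = speed * cos(dir)` with `dir` the
#' direction the wind blows *from*, so easterly and northerly winds are
#' positive); the one-hour changes in wind speed and temperature; and the
#' change in mean nightly pressure from the previous night.
#'
#' @param events Crossing events ([detect_crossings()]); may be `NULL`.
#' @param available Available hours ([sample_available()]); may be `NULL`.
#' @param deployments Deployments data.frame.
#' @param weather Weather data.frame with a `stations` attribute
#'   (`station_id, lat, lon`), as produced by [simulate_weather()]; for
#'   external weather, set the attribute before calling.
#' @return A data.frame with `tag_id, timestamp, used` and the eleven
#'   covariate columns (`hours_since_sunset, wind_speed, temperature,
#'   precipitation, visibility, pressure, wind_x, wind_y, d_wind_1h,
#'   d_temp_1h, d_pressure_24h`).
#' @export
attach_covariates <- function(events, available, deployments, weather) {
  stations <- attr(weather, "stations")
  if (is.null(stations)) stop("weather lacks a 'stations' attribute", call. = FALSE)
  rows <- list()
  if (!is.null(events) && nrow(events)) {
    rows[[1]] <- data.frame(tag_id = events$tag_id,
                            timestamp = events$midpoint_hour, used = 1L,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(available) && nrow(available)) {
    rows[[2]] <- data.frame(tag_id = available$tag_id,
                            timestamp = available$timestamp, used = 0L,
                            stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) stop("no rows to build", call. = FALSE)

  dep_idx <- match(rows$tag_id, deployments$tag_id)
  if (anyNA(dep_idx)) stop("no deployment for tag ",
                           rows$tag_id[which(is.na(dep_idx))[1]], call. = FALSE)
  lat <- deployments$release_lat[dep_idx]
  lon <- deployments$release_lon[dep_idx]
  stn <- vapply(seq_len(nrow(rows)),
                function(i) .nearest_station(lat[i], lon[i], stations), "")

  wkey <- paste(weather$station_id, as.numeric(weather$timestamp))
  widx <- match(paste(stn, as.numeric(rows$timestamp)), wkey)
  if (anyNA(widx)) {
    i <- which(is.na(widx))[1]
    stop(sprintf("missing weather for station %s at %s", stn[i],
                 .format_utc(rows$timestamp[i])), call. = FALSE)
  }
  wprev <- match(paste(stn, as.numeric(rows$timestamp) - 3600), wkey)

  # nightly mean pressure per station (hours between sunset and sunrise,
  # attributed to the night of the most recent sunset)
  nightly <- list()
  for (s in unique(stn)) {
    ws <- weather[weather$station_id == s, ]
    slat <- stations$lat[stations$station_id == s]
    slon <- stations$lon[stations$station_id == s]
    night <- is_night(ws$timestamp, slat, slon)
    nid <- night_id(ws$timestamp[night], slat, slon)
    agg <- tapply(ws$pressure[night], as.character(nid), mean)
    nightly[[s]] <- agg
  }
  # night attribution for each row: the most recent sunset's night
  # (daytime rows carry the upcoming night id; step back one night)
  nid <- night_id(rows$timestamp, lat, lon)
  row_night <- nid - (rows$timestamp < sunset_utc(nid, lat, lon))
  d_press <- vapply(seq_len(nrow(rows)), function(i) {
    cur <- nightly[[stn[i]]][as.character(row_night[i])]
    prev <- nightly[[stn[i]]][as.character(row_night[i] - 1)]
    if (is.na(cur) || is.na(prev)) NA_real_ else unname(cur - prev)
  }, 0.0)

  dir_rad <- .deg2rad(weather$wind_dir[widx])
  hss <- hours_since_sunset(rows$timestamp, lat, lon)
  out <- data.frame(
    tag_id = rows$tag_id, timestamp = rows$timestamp, used = rows$used,
    hours_since_sunset = hss,
    wind_speed = weather$wind_speed[widx],
    temperature = weather$temperature[widx],
    precipitation = weather$precipitation[widx],
    visibility = weather$visibility[widx],
    pressure = weather$pressure[widx],
    wind_x = weather$wind_speed[widx] * sin(dir_rad),
    wind_y = weather$wind_speed[widx] * cos(dir_rad),
    d_wind_1h = weather$wind_speed[widx] - weather$wind_speed[wprev],
    d_temp_1h = weather$temperature[widx] - weather$temperature[wprev],
    d_pressure_24h = d_press,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' The ten candidate atmospheric covariates
#'
#' Column names of the candidate variables entering all-subsets selection
#' (hours since sunset is held in every model, not listed here).
#'
#' @return Character vector of length 10.
#' @export
candidate_covariates <- function() {
  c("wind_speed", "temperature", "precipitation", "visibility", "pressure",
    "wind_x", "wind_y", "d_wind_1h", "d_temp_1h", "d_pressure_24h")
}
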