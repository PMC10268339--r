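# Plain-CSV interchange for the four pipeline tables. Tables are ordinary
# data.frames; timestamps are POSIXct in UTC, written back as ISO-8601 with a
# trailing Z so round-trips are exact at second resolution.

.parse_utc <- function(x, what = "timestamp") {
  x <- as.character(x)
  clean <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(strptime(clean, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(clean[miss], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row %d: '%s'", what, bad[1], x[bad[1]]),
         call. = FALSE)
  }
  out
}

.format_utc <- function(t) strftime(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

.read_checked <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (anyDuplicated(names(df))) {
    stop(sprintf("duplicate columns in %s: %s", path,
                 paste(names(df)[duplicated(names(df))], collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[required]
}

.num <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("non-numeric %s at row %d: '%s'", what, bad[1], x[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Read and write pipeline tables
#'
#' Readers validate headers, parse ISO-8601 UTC timestamps, and coerce
#' numeric columns, reporting the first offending row on failure. Writers
#' produce the same dialect, so `read(write(x))` round-trips exactly.
#'
#' `detections.csv`: `tag_id,timestamp,tower_id,antenna_id,signal_strength,run_length`.
#' `towers.csv`: `tower_id,lat,lon,water_body,side` (one row per
#' tower-waterbody adjacency; `water_body` may be empty).
#' `deployments.csv`: `tag_id,species,sex,age,release_time,release_lat,release_lon,tag_life_days`.
#' `weather.csv`: `station_id,timestamp,temperature,wind_speed,wind_dir,pressure,precipitation,visibility`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with typed columns as documented above.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_detections <- function(path) {
  df <- .read_checked(path, c("tag_id", "timestamp", "tower_id", "antenna_id",
                              "signal_strength", "run_length"))
  out <- data.frame(
    tag_id = df$tag_id,
    timestamp = .parse_utc(df$timestamp),
    tower_id = df$tower_id,
    antenna_id = df$antenna_id,
    signal_strength = .num(df$signal_strength, "signal_strength"),
    run_length = as.integer(.num(df$run_length, "run_length")),
    stringsAsFactors = FALSE
  )
  if (any(out$run_length < 1L)) stop("run_length must be >= 1", call. = FALSE)
  out
}

#' @rdname table_io
#' @param detections A detections data.frame.
#' @export
write_detections <- function(detections, path) {
  df <- detections
  df$timestamp <- .format_utc(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_towers <- function(path) {
  df <- .read_checked(path, c("tower_id", "lat", "lon", "water_body", "side"))
  out <- data.frame(
    tower_id = df$tower_id,
    lat = .num(df$lat, "lat"),
    lon = .num(df$lon, "lon"),
    water_body = ifelse(nzchar(df$water_body), df$water_body, NA_character_),
    side = ifelse(nzchar(df$side), df$side, NA_character_),
    stringsAsFactors = FALSE
  )
  .check_coords(out$lat, out$lon)
  out
}

#' @rdname table_io
#' @param towers A towers data.frame.
#' @export
write_towers <- function(towers, path) {
  df <- towers
  df$water_body[is.na(df$water_body)] <- ""
  df$side[is.na(df$side)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_deployments <- function(path) {
  df <- .read_checked(path, c("tag_id", "species", "sex", "age",
                              "release_time", "release_lat", "release_lon",
                              "tag_life_days"))
  out <- data.frame(
    tag_id = df$tag_id,
    species = df$species,
    sex = df$sex,
    age = df$age,
    release_time = .parse_utc(df$release_time, "release_time"),
    release_lat = .num(df$release_lat, "release_lat"),
    release_lon = .num(df$release_lon, "release_lon"),
    tag_life_days = .num(df$tag_life_days, "tag_life_days"),
    stringsAsFactors = FALSE
  )
  .check_coords(out$release_lat, out$release_lon)
  if (any(out$tag_life_days <= 0)) stop("tag_life_days must be > 0", call. = FALSE)
  out
}

#' @rdname table_io
#' @param deployments A deployments data.frame.
#' @export
write_deployments <- function(deployments, path) {
  df <- deployments
  df$release_time <- .format_utc(df$release_time)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_weather <- function(path) {
  df <- .read_checked(path, c("station_id", "timestamp", "temperature",
                              "wind_speed", "wind_dir", "pressure",
                              "precipitation", "visibility"))
  out <- data.frame(
    station_id = df$station_id,
    timestamp = .parse_utc(df$timestamp),
    temperature = .num(df$temperature, "temperature"),
    wind_speed = .num(df$wind_speed, "wind_speed"),
    wind_dir = .num(df$wind_dir, "wind_dir"),
    pressure = .num(df$pressure, "pressure"),
    precipitation = .num(df$precipitation, "precipitation"),
    visibility = .num(df$visibility, "visibility"),
    stringsAsFactors = FALSE
  )
  if (any(out$wind_speed < 0)) stop("wind_speed must be >= 0", call. = FALSE)
  if (any(out$visibility < 0 | out$visibility > 16)) {
    stop("visibility must lie in [0, 16] km", call. = FALSE)
  }
  out
}

#' @rdname table_io
#' @param weather A weather data.frame.
#' @export
write_weather <- function(weather, path) {
  df <- weather
  df$timestamp <- .format_utc(df$timestamp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Tower lookup with a helpful error naming the unknown id.
.tower_coords <- function(tower_ids, towers) {
  tw <- towers[!duplicated(towers$tower_id), ]
  idx <- match(tower_ids, tw$tower_id)
  if (anyNA(idx)) {
    stop(sprintf("unknown tower_id: %s",
                 paste(unique(tower_ids[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  data.frame(lat = tw$lat[idx], lon = tw$lon[idx])
}
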