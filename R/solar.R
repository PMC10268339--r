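# Solar geometry: NOAA closed-form approximation for sunrise/sunset with the
# standard zenith of 90.833 degrees (refraction + solar radius). Timestamps
# are carried in UTC throughout the pipeline; the local solar date (UTC
# shifted by lon/15 hours) only decides which calendar day's sunset applies.

.check_posixct <- function(t) {
  if (!inherits(t, "POSIXct")) stop("timestamp must be POSIXct", call. = FALSE)
  if (any(is.na(t))) stop("timestamp contains NA", call. = FALSE)
  invisible(TRUE)
}

# Fractional year (radians) at solar noon of a day-of-year.
.solar_gamma <- function(doy) 2 * pi / 365 * (doy - 1 + 0.5)

# Equation of time, minutes.
.solar_eqtime <- function(gamma) {
  229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
              0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
}

# Solar declination, radians.
.solar_decl <- function(gamma) {
  0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
}

# Sunrise/sunset instants (POSIXct UTC) for a given calendar date at a site.
# `date` is the local solar calendar date the event belongs to.
.sun_event_utc <- function(date, lat, lon, event = c("sunset", "sunrise"),
                           zenith_deg = 90.833) {
  event <- match.arg(event)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  gamma <- .solar_gamma(doy)
  eqtime <- .solar_eqtime(gamma)
  decl <- .solar_decl(gamma)
  phi <- .deg2rad(lat)
  cos_ha <- cos(.deg2rad(zenith_deg)) / (cos(phi) * cos(decl)) -
    tan(phi) * tan(decl)
  if (any(abs(cos_ha) > 1)) {
    stop("sun never rises or never sets at this latitude/date (polar regime)",
         call. = FALSE)
  }
  ha_deg <- .rad2deg(acos(cos_ha))
  sgn <- if (event == "sunset") -1 else 1
  minutes <- 720 - 4 * (lon + sgn * ha_deg) - eqtime
  as.POSIXct(unclass(date) * 86400 + minutes * 60, origin = "1970-01-01",
             tz = "UTC")
}

#' Sunset and sunrise times
#'
#' Sunset (or sunrise) instant, in UTC, belonging to a given local calendar
#' date at a site. Uses the NOAA solar-position approximation with zenith
#' 90.833 degrees.
#'
#' @param date A `Date` (vector), the local solar calendar date.
#' @param lat,lon Site coordinates in decimal degrees.
#' @return POSIXct (UTC) event times.
#' @export
sunset_utc <- function(date, lat, lon) {
  .check_coords(lat, lon)
  .sun_event_utc(date, lat, lon, "sunset")
}

#' @rdname sunset_utc
#' @export
sunrise_utc <- function(date, lat, lon) {
  .check_coords(lat, lon)
  .sun_event_utc(date, lat, lon, "sunrise")
}

# Local solar calendar date of a UTC instant (longitude/15 hour offset).
.local_solar_date <- function(t, lon) {
  as.Date(as.POSIXct(as.numeric(t) + lon / 15 * 3600,
                     origin = "1970-01-01", tz = "UTC"))
}

#' Hours since the most recent sunset
#'
#' @param t POSIXct timestamp(s), UTC.
#' @param lat,lon Site coordinates in decimal degrees.
#' @return Elapsed time since the most recent local sunset, in decimal hours
#'   (0 exactly at sunset, values above ~12 during the following day).
#' @export
hours_since_sunset <- function(t, lat, lon) {
  .check_posixct(t)
  .check_coords(lat, lon)
  n <- length(t)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  d <- .local_solar_date(t, lon)
  ss <- sunset_utc(d, lat, lon)
  over <- ss > t
  if (any(over)) ss[over] <- sunset_utc(d[over] - 1, lat[over], lon[over])
  (as.numeric(t) - as.numeric(ss)) / 3600
}

#' Night identifier of an instant
#'
#' Every instant from a sunset to the following sunrise belongs to the night
#' labelled with that sunset's local calendar date. Daytime instants are
#' assigned to the upcoming night, so the identifier increments by one day at
#' sunrise.
#'
#' @inheritParams hours_since_sunset
#' @return A `Date` vector of night identifiers.
#' @export
night_id <- function(t, lat, lon) {
  .check_posixct(t)
  .check_coords(lat, lon)
  n <- length(t)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  d <- .local_solar_date(t, lon)
  sr <- sunrise_utc(d, lat, lon)
  d - (t < sr)
}

#' Is an instant between sunset and the next sunrise?
#'
#' @inheritParams hours_since_sunset
#' @return Logical vector.
#' @export
is_night <- function(t, lat, lon) {
  .check_posixct(t)
  n <- length(t)
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  nid <- night_id(t, lat, lon)
  t >= sunset_utc(nid, lat, lon)
}

#' Cyclical encoding of an hour of day
#'
#' Maps an hour in `[0, 24)` onto the unit circle:
#' `(sin(2*pi*h/24), cos(2*pi*h/24))`. Used as transition covariates in the
#' activity hidden Markov model so that time of night wraps smoothly.
#'
#' @param h Hours, each in `[0, 24)`.
#' @return A list with numeric components `sin` and `cos`.
#' @export
cyclical_hour <- function(h) {
  if (any(!is.finite(h)) || any(h < 0 | h >= 24)) {
    stop("hour must lie in [0, 24)", call. = FALSE)
  }
  ang <- 2 * pi * h / 24
  list(sin = sin(ang), cos = cos(ang))
}
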