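# Spherical-earth geodesy. All thresholds in this pipeline (12 km residency,
# 50 km migration, 1,000 km implausibility) are coarse enough that a sphere
# of radius 6371 km is adequate; no ellipsoid is used anywhere.

.EARTH_RADIUS_KM <- 6371.0

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.check_coords <- function(lat, lon) {
  if (!all(is.finite(lat)) || !all(is.finite(lon))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) stop("latitude out of [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude out of [-180, 180]", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over all four
#' arguments with the usual recycling rules.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in kilometres.
#' @examples
#' haversine_km(0, 0, 0, 1)  # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- .deg2rad(lat2 - lat1)
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * .EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Bearing from the first point toward the second, measured clockwise from
#' north, in `[0, 360)`. Undefined for coincident points.
#'
#' @inheritParams haversine_km
#' @return Bearing(s) in degrees.
#' @export
initial_bearing_deg <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  if (any(lat1 == lat2 & lon1 == lon2)) {
    stop("bearing undefined for coincident points", call. = FALSE)
  }
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  (.rad2deg(atan2(y, x)) + 360) %% 360
}

#' Destination point given start, bearing, and distance
#'
#' Used by the trajectory simulator to step bats along great circles.
#'
#' @param lat,lon Start coordinates, decimal degrees.
#' @param bearing_deg Initial bearing, degrees clockwise from north.
#' @param distance_km Distance travelled, km.
#' @return A list with elements `lat` and `lon`.
#' @export
destination_point <- function(lat, lon, bearing_deg, distance_km) {
  .check_coords(lat, lon)
  delta <- distance_km / .EARTH_RADIUS_KM
  theta <- .deg2rad(bearing_deg)
  phi1 <- .deg2rad(lat); lam1 <- .deg2rad(lon)
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  list(lat = .rad2deg(phi2), lon = ((.rad2deg(lam2) + 540) %% 360) - 180)
}

#' Circular (vector) mean of bearings
#'
#' @param bearings_deg Bearings in degrees.
#' @return Mean direction in `[0, 360)`, or `NA_real_` when the resultant
#'   vector length is numerically zero (the mean direction is undefined,
#'   e.g. for `c(90, 270)`).
#' @export
circular_mean_deg <- function(bearings_deg) {
  if (length(bearings_deg) == 0) return(NA_real_)
  s <- mean(sin(.deg2rad(bearings_deg)))
  c <- mean(cos(.deg2rad(bearings_deg)))
  if (sqrt(s^2 + c^2) < 1e-10) return(NA_real_)
  (.rad2deg(atan2(s, c)) + 360) %% 360
}
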