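# Rule-based movement classification. Categories follow the field
# definitions: migration is a >50 km displacement between towers without a
# later return near the origin; site residency is local (<12 km) detection
# spanning more than one night; a long-distance return is a >50 km excursion
# followed by detection back near the origin.

#' Classify migration behavior of one cleaned track
#'
#' "migrant" when some later tower lies more than `threshold_km` from an
#' earlier detection location and no subsequent detection returns within
#' `return_radius_km` of that earlier location; "long_distance_return" when
#' the long excursion exists but the track later comes back near the origin;
#' "neither" otherwise. A documented return takes precedence: a track that
#' leaves, exceeds the threshold, and is later detected back near the
#' excursion's origin is a long-distance return, even though the homeward
#' leg itself is a >`threshold_km` displacement with no subsequent
#' back-tracking (counting that leg as migration would misread every
#' round trip).
#'
#' @param detections Cleaned, time-ordered detections for one tag.
#' @param towers Towers data.frame.
#' @param threshold_km Displacement defining long-distance travel (default 50).
#' @param return_radius_km Radius counting as a return to the earlier
#'   location (default 12, the residency radius).
#' @return One of `"migrant"`, `"long_distance_return"`, `"neither"`.
#' @export
classify_migration <- function(detections, towers, threshold_km = 50,
                               return_radius_km = 12) {
  if (nrow(detections) == 0) stop("track has no detections", call. = FALSE)
  # The scan is exact but works at the tower level: an excursion (detection
  # at A before a detection at B with dist(A,B) > threshold) exists iff
  # first(A) < last(B); a return for origin A exists iff some far tower B
  # has a detection strictly between first(A) and the latest detection time
  # at any tower within return_radius_km of A.
  ord <- order(detections$timestamp)
  tid <- detections$tower_id[ord]
  tt <- as.numeric(detections$timestamp[ord])
  uti <- !duplicated(tid)
  utow <- tid[uti]
  uco <- .tower_coords(utow, towers)
  first_t <- tapply(tt, tid, min)[utow]
  last_t <- tapply(tt, tid, max)[utow]
  times_by <- split(tt, tid)
  nu <- length(utow)
  found_excursion <- FALSE
  found_return <- FALSE
  for (a in seq_len(nu)) {
    d <- haversine_km(uco$lat[a], uco$lon[a], uco$lat, uco$lon)
    far <- which(d > threshold_km)
    if (!length(far)) next
    if (any(first_t[a] < last_t[far])) found_excursion <- TRUE
    last_near <- max(last_t[d <= return_radius_km])
    for (b in far) {
      tb <- times_by[[utow[b]]]
      if (any(tb > first_t[a] & tb < last_near)) {
        found_return <- TRUE
        break
      }
    }
    if (found_return) break
  }
  if (found_return) "long_distance_return"
  else if (found_excursion) "migrant"
  else "neither"
}

#' Classify site residency of one cleaned track
#'
#' Resident when detections at towers closer than `radius_km` to the release
#' point span more than one night. Minimum residency time is the whole-day
#' calendar difference between the tagging date and the last local-detection
#' date (a bat only seen on its release night scores 0).
#'
#' @param detections Cleaned, time-ordered detections for one tag.
#' @param deployment One-row deployment data.frame.
#' @param towers Towers data.frame.
#' @param radius_km Local radius around the release point (default 12;
#'   strictly less-than).
#' @return A list with `resident` (logical) and `min_residency_days`
#'   (integer, `NA` when there are no local detections).
#' @export
classify_residency <- function(detections, deployment, towers, radius_km = 12) {
  if (nrow(detections) == 0) {
    return(list(resident = FALSE, min_residency_days = NA_integer_))
  }
  co <- .tower_coords(detections$tower_id, towers)
  local <- haversine_km(co$lat, co$lon, deployment$release_lat,
                        deployment$release_lon) < radius_km
  if (!any(local)) {
    return(list(resident = FALSE, min_residency_days = NA_integer_))
  }
  loc <- detections[local, , drop = FALSE]
  nights <- unique(night_id(loc$timestamp, deployment$release_lat,
                            deployment$release_lon))
  resident <- length(nights) > 1
  last_date <- max(as.Date(loc$timestamp, tz = "UTC"))
  release_date <- as.Date(deployment$release_time, tz = "UTC")
  days <- as.integer(last_date - release_date)
  list(resident = resident, min_residency_days = max(days, 0L))
}

#' Bearing of travel for a migrant
#'
#' Initial great-circle bearing from the release coordinates to the tower of
#' the last detection.
#'
#' @inheritParams classify_residency
#' @return Bearing in degrees `[0, 360)`.
#' @export
travel_bearing <- function(detections, deployment, towers) {
  if (nrow(detections) == 0) stop("track has no detections", call. = FALSE)
  last <- detections[which.max(as.numeric(detections$timestamp)), ]
  co <- .tower_coords(last$tower_id, towers)
  initial_bearing_deg(deployment$release_lat, deployment$release_lon,
                      co$lat, co$lon)
}

#' Per-tag behavior summaries for a cohort
#'
#' Cleans nothing; expects already-cleaned detections. Returns one row per
#' deployed tag with detection status, residency, migration category, the
#' travel bearing (defined only for migrants), and the minimum residency
#' time.
#'
#' @param detections Cleaned detections data.frame (all tags).
#' @param deployments Deployments data.frame.
#' @param towers Towers data.frame.
#' @param threshold_km,return_radius_km,radius_km Classification thresholds;
#'   see [classify_migration()] and [classify_residency()].
#' @return A data.frame with columns `tag_id, detected, resident, migrant,
#'   long_distance_return, bearing_deg, min_residency_days, last_tower_id,
#'   last_detection_time`.
#' @export
summarize_behavior <- function(detections, deployments, towers,
                               threshold_km = 50, return_radius_km = 12,
                               radius_km = 12) {
  out <- lapply(seq_len(nrow(deployments)), function(i) {
    dep <- deployments[i, , drop = FALSE]
    det <- detections[detections$tag_id == dep$tag_id, , drop = FALSE]
    det <- det[order(det$timestamp), , drop = FALSE]
    if (nrow(det) == 0) {
      return(data.frame(tag_id = dep$tag_id, detected = FALSE,
                        resident = FALSE, migrant = FALSE,
                        long_distance_return = FALSE, bearing_deg = NA_real_,
                        min_residency_days = NA_integer_,
                        last_tower_id = NA_character_,
                        last_detection_time = as.POSIXct(NA, tz = "UTC"),
                        stringsAsFactors = FALSE))
    }
    mig <- classify_migration(det, towers, threshold_km, return_radius_km)
    res <- classify_residency(det, dep, towers, radius_km)
    bearing <- if (mig == "migrant") travel_bearing(det, dep, towers) else NA_real_
    last <- det[nrow(det), ]
    data.frame(tag_id = dep$tag_id, detected = TRUE,
               resident = res$resident, migrant = mig == "migrant",
               long_distance_return = mig == "long_distance_return",
               bearing_deg = bearing,
               min_residency_days = res$min_residency_days,
               last_tower_id = last$tower_id,
               last_detection_time = last$timestamp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort-level summary of behavior classifications
#'
#' Counts by category, the circular (vector) mean and range of migrant
#' bearings, and the mean and 0.05/0.95 linear-interpolation quantiles of
#' minimum residency times.
#'
#' @param summaries Output of [summarize_behavior()].
#' @return A list (`cohort_summary`): counts `n_tagged, n_detected,
#'   n_migrant, n_resident, n_both, n_return`; `mean_bearing_deg` (`NA` and
#'   `bearing_undefined = TRUE` when the resultant is numerically zero),
#'   `min_bearing_deg`, `max_bearing_deg`; `residency_mean_days`,
#'   `residency_q05`, `residency_q95`.
#' @export
summarize_cohort <- function(summaries) {
  if (nrow(summaries) == 0) stop("no summaries supplied", call. = FALSE)
  bearings <- summaries$bearing_deg[!is.na(summaries$bearing_deg)]
  res <- summaries$min_residency_days[summaries$resident &
                                        !is.na(summaries$min_residency_days)]
  mean_b <- circular_mean_deg(bearings)
  q <- if (length(res)) stats::quantile(res, c(0.05, 0.95), names = FALSE,
                                        type = 7) else c(NA_real_, NA_real_)
  list(
    n_tagged = nrow(summaries),
    n_detected = sum(summaries$detected),
    n_migrant = sum(summaries$migrant),
    n_resident = sum(summaries$resident),
    n_both = sum(summaries$migrant & summaries$resident),
    n_return = sum(summaries$long_distance_return),
    mean_bearing_deg = mean_b,
    bearing_undefined = length(bearings) > 0 && is.na(mean_b),
    min_bearing_deg = if (length(bearings)) min(bearings) else NA_real_,
    max_bearing_deg = if (length(bearings)) max(bearings) else NA_real_,
    residency_mean_days = if (length(res)) mean(res) else NA_real_,
    residency_q05 = q[1],
    residency_q95 = q[2]
  )
}
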