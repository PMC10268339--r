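# Detection-cleaning cascade for automated radio telemetry. Three filters:
# short reception runs (likely noise), towers implausibly far from the rest
# of the track (false positives), and a steady terminal signal (a shed tag
# lying near a tower). Each filter returns a subsequence of its input and is
# idempotent.

#' Drop short detection runs
#'
#' Retains detections whose reception run length (number of sequential
#' detections of the tag in one burst at one tower) is at least `min_run`;
#' with the default this keeps runs of length strictly greater than 3.
#'
#' @param detections Detections data.frame (see [read_detections()]).
#' @param min_run Minimum run length retained (default 4).
#' @return The filtered detections data.frame.
#' @export
filter_run_length <- function(detections, min_run = 4L) {
  detections[detections$run_length >= min_run, , drop = FALSE]
}

#' Drop detections at implausibly distant towers
#'
#' A detection is treated as a false positive and removed when its tower is
#' more than `max_km` from the release point *and* from the towers of both
#' its temporal neighbours among the retained detections. Removal iterates to
#' a fixed point so the result does not depend on scan order.
#'
#' @param detections Time-ordered detections data.frame for one tag.
#' @param deployment One-row deployment data.frame for the same tag.
#' @param towers Towers data.frame.
#' @param max_km Distance threshold in km (default 1000; strictly greater
#'   removes).
#' @return The filtered detections data.frame.
#' @export
filter_implausible <- function(detections, deployment, towers, max_km = 1000) {
  if (nrow(detections) == 0) return(detections)
  co <- .tower_coords(detections$tower_id, towers)
  d_release <- haversine_km(co$lat, co$lon,
                            deployment$release_lat, deployment$release_lon)
  keep <- rep(TRUE, nrow(detections))
  repeat {
    idx <- which(keep)
    far <- idx[d_release[idx] > max_km]
    if (!length(far)) break
    changed <- FALSE
    pos <- match(far, idx)
    for (k in seq_along(far)) {
      i <- far[k]
      j <- pos[k]
      ok <- FALSE
      if (j > 1) {
        p <- idx[j - 1]
        if (haversine_km(co$lat[i], co$lon[i], co$lat[p], co$lon[p]) <= max_km) ok <- TRUE
      }
      if (!ok && j < length(idx)) {
        nx <- idx[j + 1]
        if (haversine_km(co$lat[i], co$lon[i], co$lat[nx], co$lon[nx]) <= max_km) ok <- TRUE
      }
      if (!ok) {
        keep[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  detections[keep, , drop = FALSE]
}

#' Trim a steady terminal segment (tag drop)
#'
#' A tag shed near a tower keeps transmitting with near-constant signal.
#' Within the terminal contiguous run of detections at a single
#' tower/antenna, the longest terminal window whose signal-strength standard
#' deviation is at most `steady_sd_tol` is located; if that window spans at
#' least `steady_days` days it is removed. The check repeats on the new
#' track end until nothing more is trimmed, so the filter is idempotent.
#'
#' @param detections Time-ordered detections data.frame for one tag.
#' @param steady_days Minimum span in days for a segment to count as steady
#'   (default 7).
#' @param steady_sd_tol Signal SD at or below which a segment counts as
#'   steady. Default: 5% of the whole-track signal SD (0 if that SD is 0).
#' @return The trimmed detections data.frame.
#' @export
trim_tag_drop <- function(detections, steady_days = 7, steady_sd_tol = NULL) {
  if (nrow(detections) < 2) return(detections)
  if (is.null(steady_sd_tol)) {
    whole_sd <- stats::sd(detections$signal_strength)
    steady_sd_tol <- if (is.na(whole_sd)) 0 else 0.05 * whole_sd
  }
  repeat {
    n <- nrow(detections)
    if (n < 2) break
    key <- paste(detections$tower_id, detections$antenna_id)
    start <- n
    while (start > 1 && key[start - 1] == key[n]) start <- start - 1
    xs <- detections$signal_strength[start:n]
    m <- length(xs)
    # SD of every terminal window xs[i..m], via reversed cumulative sums
    cnt <- m:1
    s1 <- rev(cumsum(rev(xs)))
    s2 <- rev(cumsum(rev(xs^2)))
    v <- (s2 - s1^2 / cnt) / pmax(cnt - 1, 1)
    sdw <- sqrt(pmax(v, 0))
    sdw[cnt == 1] <- 0
    steady <- which(sdw <= steady_sd_tol)
    if (!length(steady)) break
    i <- min(steady)  # the longest steady terminal window
    span_days <- as.numeric(difftime(detections$timestamp[n],
                                     detections$timestamp[start + i - 1],
                                     units = "days"))
    if (span_days >= steady_days) {
      detections <- detections[-((start + i - 1):n), , drop = FALSE]
    } else {
      break
    }
  }
  detections
}

#' Apply the full cleaning cascade to one tag's detections
#'
#' Run-length filter, implausible-distance filter, then tag-drop trim, in
#' that order, with per-stage record counts attached for auditability.
#'
#' @inheritParams filter_implausible
#' @param min_run,max_km,steady_days,steady_sd_tol Thresholds passed to the
#'   individual filters.
#' @return The cleaned detections data.frame with attribute `clean_counts`
#'   (named integer vector of record counts after each stage).
#' @export
clean_track <- function(detections, deployment, towers, min_run = 4L,
                        max_km = 1000, steady_days = 7, steady_sd_tol = NULL) {
  n0 <- nrow(detections)
  detections <- detections[order(detections$timestamp), , drop = FALSE]
  d1 <- filter_run_length(detections, min_run)
  d2 <- filter_implausible(d1, deployment, towers, max_km)
  d3 <- trim_tag_drop(d2, steady_days, steady_sd_tol)
  attr(d3, "clean_counts") <- c(input = n0, run_length = nrow(d1),
                                implausible = nrow(d2), tag_drop = nrow(d3))
  d3
}
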