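# End-to-end orchestration: simulate -> clean -> classify -> over-water
# selection -> activity HMM -> report. Every stage writes its interface
# files under out_dir and logs in/out record counts to a run manifest, so
# the cleaning cascade is auditable.

#' Run the full analysis pipeline on a synthetic scenario
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("simulate", "clean", "classify", "rsf", "hmm", "report")`. Stages
#'   build on earlier ones; disabling an intermediate stage also skips the
#'   stages that need its output.
#' @param ratio,horizon_days Availability design (defaults 10 and 40).
#' @param candidate_vars Candidate covariates for the all-subsets search
#'   (default all ten; shrink for a faster run).
#' @param min_days,max_gap_days Residency filter for the activity stage.
#' @param hmm_restarts Restarts per HMM fit (default 5 for pipeline runs).
#' @return Invisibly, a list with all stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir = "results",
                         stages = c("simulate", "clean", "classify", "rsf",
                                    "hmm", "report"),
                         ratio = 10, horizon_days = 40,
                         candidate_vars = candidate_covariates(),
                         min_days = 20, max_gap_days = 2, hmm_restarts = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, stages = stages, timings = list(),
                   counts = list())
  out <- list()
  tick <- function(name, expr) {
    s <- Sys.time()
    v <- expr
    manifest$timings[[name]] <<- round(as.numeric(Sys.time() - s, units = "secs"), 2)
    v
  }

  stopifnot(all(stages %in% c("simulate", "clean", "classify", "rsf", "hmm",
                              "report")))
  if (!"simulate" %in% stages) stop("pipeline currently starts from simulate",
                                    call. = FALSE)
  sc <- tick("simulate", simulate_scenario(config))
  out$scenario <- sc
  write_detections(sc$detections, file.path(out_dir, "detections.csv"))
  write_towers(sc$towers, file.path(out_dir, "towers.csv"))
  write_deployments(sc$deployments, file.path(out_dir, "deployments.csv"))
  write_weather(sc$weather, file.path(out_dir, "weather.csv"))
  manifest$counts$detections_raw <- nrow(sc$detections)

  if (!"clean" %in% stages) return(.finish_pipeline(out, manifest, out_dir, t0))
  cleaned <- tick("clean", {
    parts <- lapply(seq_len(nrow(sc$deployments)), function(i) {
      dep <- sc$deployments[i, , drop = FALSE]
      det <- sc$detections[sc$detections$tag_id == dep$tag_id, , drop = FALSE]
      clean_track(det, dep, sc$towers)
    })
    do.call(rbind, parts)
  })
  out$cleaned <- cleaned
  write_detections(cleaned, file.path(out_dir, "detections_clean.csv"))
  manifest$counts$detections_clean <- nrow(cleaned)

  if ("classify" %in% stages) {
    summaries <- tick("classify",
                      summarize_behavior(cleaned, sc$deployments, sc$towers))
    cohort <- summarize_cohort(summaries)
    out$summaries <- summaries
    out$cohort <- cohort
    bs <- summaries
    bs$last_detection_time <- .format_utc(bs$last_detection_time)
    utils::write.csv(bs, file.path(out_dir, "behavior_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cohort, file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$counts$n_detected <- cohort$n_detected
    manifest$counts$n_migrant <- cohort$n_migrant
    manifest$counts$n_resident <- cohort$n_resident
  }

  if ("rsf" %in% stages) {
    rsf <- tick("rsf", {
      events <- detect_crossings(cleaned, sc$towers, sc$deployments)
      avail <- sample_available(events, sc$deployments, ratio = ratio,
                                horizon_days = horizon_days,
                                seed = config$seed + 101L)
      rows <- if (nrow(events)) {
        attach_covariates(events, avail, sc$deployments, sc$weather)
      } else {
        NULL
      }
      dr <- if (!is.null(rows)) dredge_aicc(rows, candidate_vars) else NULL
      list(events = events, avail = avail, rows = rows, dredge = dr)
    })
    out$rsf <- rsf
    ev <- rsf$events
    for (cc in c("departure_time", "arrival_time", "midpoint_hour")) {
      ev[[cc]] <- .format_utc(ev[[cc]])
    }
    utils::write.csv(ev, file.path(out_dir, "crossings.csv"),
                     row.names = FALSE)
    if (!is.null(rsf$rows)) {
      ua <- rsf$rows
      ua$timestamp <- .format_utc(ua$timestamp)
      utils::write.csv(ua, file.path(out_dir, "use_avail.csv"),
                       row.names = FALSE)
      utils::write.csv(rsf$dredge$table, file.path(out_dir, "rsf_models.csv"),
                       row.names = FALSE)
      top <- rsf$dredge$fits[[1]]
      me <- do.call(rbind, lapply(top$variable_subset, function(v) {
        cbind(variable = v, marginal_effects(top, rsf$rows, v))
      }))
      utils::write.csv(me, file.path(out_dir, "marginal_effects.csv"),
                       row.names = FALSE)
      manifest$counts$n_used <- top$n_used
      manifest$counts$n_available <- top$n_available
      manifest$counts$n_rsf_models <- rsf$dredge$n_models
    }
  }

  if ("hmm" %in% stages && !is.null(out$summaries)) {
    hmm <- tick("hmm", {
      resid_tags <- select_residents(out$summaries, cleaned, sc$deployments,
                                     sc$towers, min_days = min_days,
                                     max_gap_days = max_gap_days)
      fits <- list(); series_all <- list(); decoded <- list(); trends <- list()
      for (tag in resid_tags) {
        dep <- sc$deployments[sc$deployments$tag_id == tag, , drop = FALSE]
        det <- cleaned[cleaned$tag_id == tag, , drop = FALSE]
        ser <- build_activity_series(det, dep, sc$towers, sc$weather)
        if (nrow(ser) < 48) next
        fit <- fit_hmm(ser, restarts = hmm_restarts,
                       seed = config$seed + 211L)
        fits[[tag]] <- fit
        series_all[[tag]] <- ser
        decoded[[tag]] <- data.frame(tag_id = tag, hour = ser$hour,
                                     state = fit$decoded_states,
                                     stringsAsFactors = FALSE)
        trends[[tag]] <- cbind(tag_id = tag,
                               state_condition_trends(fit$decoded_states, ser,
                                                      dep$release_lat,
                                                      dep$release_lon))
      }
      list(tags = resid_tags, fits = fits, series = series_all,
           decoded = decoded, trends = trends)
    })
    out$hmm <- hmm
    if (length(hmm$series)) {
      ser <- do.call(rbind, hmm$series)
      ser$hour <- .format_utc(ser$hour)
      utils::write.csv(ser, file.path(out_dir, "activity_series.csv"),
                       row.names = FALSE)
      dec <- do.call(rbind, hmm$decoded)
      dec$hour <- .format_utc(dec$hour)
      utils::write.csv(dec, file.path(out_dir, "decoded_states.csv"),
                       row.names = FALSE)
      utils::write.csv(do.call(rbind, hmm$trends),
                       file.path(out_dir, "trends.csv"), row.names = FALSE)
      jsonlite::write_json(
        lapply(hmm$fits, function(f) f[c("state_means", "state_sds",
                                         "init_prob", "trans_coef",
                                         "log_likelihood", "n_iters",
                                         "converged")]),
        file.path(out_dir, "hmm_fits.json"), auto_unbox = TRUE, digits = NA)
      manifest$counts$n_hmm_bats <- length(hmm$fits)
    }
  }

  if ("report" %in% stages && !is.null(out$summaries)) {
    out$report <- tick("report", report_bundle(out))
    jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  .finish_pipeline(out, manifest, out_dir, t0)
}

.finish_pipeline <- function(out, manifest, out_dir, t0) {
  manifest$total_secs <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  cfgfile <- tempfile()
  writeLines(jsonlite::toJSON(manifest$counts, auto_unbox = TRUE), cfgfile)
  manifest$config_hash <- unname(tools::md5sum(cfgfile))
  unlink(cfgfile)
  out$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Summary report bundle
#'
#' Tabulates cohort counts and proportions, migrant bearing histogram data,
#' kernel densities of crossing and migration timing over the season, the
#' top selection model's coefficients, and the activity-state trends — the
#' numeric content of the study's standard figures.
#'
#' @param out A pipeline output list (from [run_pipeline()]).
#' @return A list of report sections.
#' @export
report_bundle <- function(out) {
  cohort <- out$cohort
  rep <- list(overall = cohort)
  bearings <- out$summaries$bearing_deg[!is.na(out$summaries$bearing_deg)]
  rep$bearing_histogram <- if (length(bearings)) {
    h <- graphics::hist(bearings, breaks = seq(0, 360, 30), plot = FALSE)
    list(breaks = h$breaks, counts = h$counts)
  } else {
    list(note = "undefined (no migrant bearings)")
  }
  if (!is.null(out$rsf) && nrow(out$rsf$events)) {
    doy <- as.integer(strftime(out$rsf$events$night_id, "%j"))
    if (length(doy) >= 2 && stats::sd(doy) > 0) {
      d <- stats::density(doy, bw = "nrd0")
      rep$crossing_timing_density <- list(day_of_year = d$x, density = d$y)
    }
    top <- out$rsf$dredge$fits[[1]]
    rep$top_model <- list(variables = top$variable_subset,
                          beta = as.list(top$beta), se = as.list(top$se),
                          z = as.list(top$z), p = as.list(top$p),
                          aicc = top$aicc,
                          n_within_2_delta = sum(out$rsf$dredge$retained))
  }
  mig_dates <- out$summaries$last_detection_time[out$summaries$migrant]
  mig_dates <- mig_dates[!is.na(mig_dates)]
  if (length(mig_dates) >= 2) {
    doy <- as.integer(strftime(mig_dates, "%j", tz = "UTC"))
    if (stats::sd(doy) > 0) {
      d <- stats::density(doy, bw = "nrd0")
      rep$migration_timing_density <- list(day_of_year = d$x, density = d$y)
    }
  }
  if (!is.null(out$hmm) && length(out$hmm$trends)) {
    rep$activity_trends <- do.call(rbind, out$hmm$trends)
  }
  rep
}
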