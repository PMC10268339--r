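#!/usr/bin/env Rscript
# Stage 5 -- cohort report and figures.
# Runs the whole pipeline in one pass (stages reuse the same seed, so this
# is consistent with the per-stage scripts), writes the JSON report bundle,
# and draws the standard figures: bearing histogram, seasonal timing
# densities of crossings vs migration, marginal-effect curves of the top
# selection model, and decoded state-vs-condition scatter with logistic
# trends.

suppressPackageStartupMessages({
  library(batmotus)
  library(ggplot2)
})
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

out <- run_pipeline(scenario_config(seed = seed), out_dir = "results")
dir.create("results/figures", showWarnings = FALSE)

co <- out$cohort
cat(sprintf("Cohort: %d tagged, %d detected, %d migrants (bearing %.0f deg), %d residents (mean %.1f d)\n",
            co$n_tagged, co$n_detected, co$n_migrant, co$mean_bearing_deg,
            co$n_resident, co$residency_mean_days))

b <- out$summaries$bearing_deg
b <- b[!is.na(b)]
if (length(b)) {
  ggsave("results/figures/bearings.png",
         ggplot(data.frame(bearing = b), aes(bearing)) +
           geom_histogram(breaks = seq(0, 360, 15), fill = "grey40") +
           coord_polar() +
           scale_x_continuous(limits = c(0, 360),
                              breaks = seq(0, 315, 45)) +
           labs(title = "Migration bearings", x = NULL, y = "bats") +
           theme_minimal(),
         width = 5, height = 5, dpi = 120)
}

if (!is.null(out$rsf) && nrow(out$rsf$events) > 2) {
  ev_doy <- as.integer(strftime(out$rsf$events$night_id, "%j"))
  mig <- out$summaries$last_detection_time[out$summaries$migrant]
  mig_doy <- as.integer(strftime(mig[!is.na(mig)], "%j", tz = "UTC"))
  df <- rbind(data.frame(doy = ev_doy, what = "over-water flight"),
              data.frame(doy = mig_doy, what = "migration"))
  ggsave("results/figures/timing_density.png",
         ggplot(df, aes(doy, colour = what)) + geom_density() +
           labs(x = "day of year", y = "density", colour = NULL) +
           theme_minimal(),
         width = 6, height = 4, dpi = 120)

  top <- out$rsf$dredge$fits[[1]]
  me <- do.call(rbind, lapply(top$variable_subset, function(v) {
    cbind(variable = v, marginal_effects(top, out$rsf$rows, v))
  }))
  ggsave("results/figures/marginal_effects.png",
         ggplot(me, aes(value, prob)) +
           geom_ribbon(aes(ymin = lower95, ymax = upper95), fill = "grey80") +
           geom_line() +
           facet_wrap(~variable, scales = "free_x") +
           labs(x = NULL, y = "relative probability of over-water flight") +
           theme_minimal(),
         width = 8, height = 6, dpi = 120)
}

if (!is.null(out$hmm) && length(out$hmm$decoded)) {
  dd <- do.call(rbind, lapply(names(out$hmm$decoded), function(tag) {
    ser <- out$hmm$series[[tag]]
    data.frame(tag_id = tag, state = out$hmm$decoded[[tag]]$state,
               temperature = ser$temperature, hss = ser$hss,
               wind_speed = ser$wind_speed)
  }))
  dd <- dd[dd$hss <= 12, ]
  long <- rbind(
    data.frame(tag_id = dd$tag_id, state = dd$state, x = dd$temperature,
               var = "temperature (C)"),
    data.frame(tag_id = dd$tag_id, state = dd$state, x = dd$hss,
               var = "hours since sunset"),
    data.frame(tag_id = dd$tag_id, state = dd$state, x = dd$wind_speed,
               var = "wind speed (m/s)")
  )
  long$active <- as.integer(long$state == "active")
  ggsave("results/figures/state_trends.png",
         ggplot(long, aes(x, active)) +
           geom_jitter(aes(colour = tag_id), height = 0.08, alpha = 0.4,
                       size = 0.7) +
           geom_smooth(method = "glm",
                       method.args = list(family = "binomial"),
                       colour = "black", se = FALSE) +
           facet_wrap(~var, scales = "free_x") +
           labs(x = NULL, y = "predicted state (0 = rest, 1 = active)") +
           guides(colour = "none") + theme_minimal(),
         width = 8, height = 4, dpi = 120)
}

cat("Report bundle written to results/report.json; figures under results/figures/\n")
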