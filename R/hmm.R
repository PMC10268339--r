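# Two-state hidden Markov model of hourly signal-strength variability with
# covariate-dependent transitions. Emissions are Gaussian per state; each
# hour's 2x2 transition matrix puts the probability of being active next at
# inverse-logit(alpha_i + bsin_i * sin + bcos_i * cos) for origin state i,
# where sin/cos encode hours since sunset on a 24 h cycle. Fitting is EM
# (scaled forward-backward; M-step = weighted Gaussian updates and weighted
# logistic regressions on expected transitions), best of several seeded
# restarts. Independent contiguity segments are separate chains sharing
# parameters. State 2 is "active" by the convention mu_active > mu_rest.

#' Select long-residency individuals for activity modelling
#'
#' Keeps tags classified resident for more than `min_days` whose local
#' detection dates contain no gap longer than `max_gap_days`.
#'
#' @param summaries Behavior summaries from [summarize_behavior()].
#' @param detections Cleaned detections data.frame.
#' @param deployments Deployments data.frame.
#' @param towers Towers data.frame.
#' @param min_days Residency-days threshold (strictly greater; default 20).
#' @param max_gap_days Largest tolerated gap between successive local
#'   detection dates (default 2).
#' @param radius_km Local radius (default 12).
#' @return Character vector of retained tag ids.
#' @export
select_residents <- function(summaries, detections, deployments, towers,
                             min_days = 20, max_gap_days = 2, radius_km = 12) {
  cand <- summaries$tag_id[summaries$resident &
                             !is.na(summaries$min_residency_days) &
                             summaries$min_residency_days > min_days]
  keep <- character(0)
  for (tag in cand) {
    dep <- deployments[deployments$tag_id == tag, , drop = FALSE]
    det <- detections[detections$tag_id == tag, , drop = FALSE]
    co <- .tower_coords(det$tower_id, towers)
    local <- haversine_km(co$lat, co$lon, dep$release_lat, dep$release_lon) <
      radius_km
    dates <- sort(unique(as.Date(det$timestamp[local], tz = "UTC")))
    if (length(dates) < 2) next
    # successive dates d and d+k straddle k-1 days without detections
    if (max(diff(as.integer(dates))) - 1 <= max_gap_days) keep <- c(keep, tag)
  }
  keep
}

#' Hourly activity series from signal-strength variability
#'
#' Per tower-antenna, signal strengths are divided by that antenna's overall
#' SD (a zero-SD antenna is excluded with a warning); readings are binned by
#' the tower's local clock hour; within each hour each antenna with at least
#' two readings contributes the SD of its scaled values; the hour's value is
#' the mean over contributing antennas. Hours with no contributing antenna
#' are missing (not zero). Contiguity segments split at gaps longer than 6
#' hours.
#'
#' @param detections Cleaned detections for one tag.
#' @param deployment One-row deployment (release site gives the sunset
#'   clock).
#' @param towers Towers data.frame (tower longitudes give local clock
#'   offsets).
#' @param weather Optional weather data.frame (with `stations` attribute) to
#'   attach `temperature` and `wind_speed` covariates.
#' @param gap_hours Segment-splitting gap (default 6).
#' @return A data.frame `tag_id, hour, value, hss, hss_sin, hss_cos,
#'   temperature, wind_speed, segment_id`, ordered by hour. `hour` is the
#'   UTC instant at which the local clock hour begins.
#' @export
build_activity_series <- function(detections, deployment, towers,
                                  weather = NULL, gap_hours = 6) {
  if (nrow(detections) < 2) stop("need >= 2 detections", call. = FALSE)
  co <- .tower_coords(detections$tower_id, towers)
  # local clock hour of the tower (whole-hour standard offset)
  offset_s <- round(co$lon / 15) * 3600
  local_bin <- floor((as.numeric(detections$timestamp) + offset_s) / 3600)
  hour_utc <- .floor_hour(as.POSIXct(local_bin * 3600 - offset_s,
                                     origin = "1970-01-01", tz = "UTC"))
  ant <- paste(detections$tower_id, detections$antenna_id, sep = "/")
  scaled <- rep(NA_real_, nrow(detections))
  for (a in unique(ant)) {
    i <- which(ant == a)
    s <- stats::sd(detections$signal_strength[i])
    if (is.na(s) || s == 0) {
      warning("antenna ", a, " has zero signal SD; excluded")
      next
    }
    scaled[i] <- detections$signal_strength[i] / s
  }
  ok <- !is.na(scaled)
  key <- paste(as.numeric(hour_utc), ant)
  per_ant <- tapply(scaled[ok], key[ok], function(v)
    if (length(v) >= 2) stats::sd(v) else NA_real_)
  kh <- as.numeric(vapply(strsplit(names(per_ant), " "), `[`, "", 1))
  vals <- tapply(unname(per_ant), kh, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  hours <- as.POSIXct(as.numeric(names(vals)), origin = "1970-01-01",
                      tz = "UTC")
  keep <- !is.na(vals)
  hours <- hours[keep]; vals <- as.numeric(vals[keep])
  ord <- order(hours)
  hours <- hours[ord]; vals <- vals[ord]

  mid <- hours + 1800
  hss <- hours_since_sunset(mid, deployment$release_lat,
                            deployment$release_lon)
  cyc <- cyclical_hour(hss %% 24)
  gaps <- c(0, diff(as.numeric(hours)) / 3600)
  segment_id <- cumsum(gaps > gap_hours) + 1L

  temperature <- wind_speed <- rep(NA_real_, length(hours))
  if (!is.null(weather)) {
    stations <- attr(weather, "stations")
    stn <- .nearest_station(deployment$release_lat, deployment$release_lon,
                            stations)
    widx <- match(paste(stn, as.numeric(.floor_hour(hours))),
                  paste(weather$station_id, as.numeric(weather$timestamp)))
    temperature <- weather$temperature[widx]
    wind_speed <- weather$wind_speed[widx]
  }
  data.frame(tag_id = deployment$tag_id, hour = hours, value = vals,
             hss = hss, hss_sin = cyc$sin, hss_cos = cyc$cos,
             temperature = temperature, wind_speed = wind_speed,
             segment_id = segment_id, stringsAsFactors = FALSE)
}

# Per-hour transition matrices from coefficients and covariates.
# Returns an array T x 2 x 2; [t, i, j] = P(state_t = j | state_{t-1} = i),
# states (1 = rest, 2 = active); row [t, i, ] uses covariates at arrival t.
.hmm_trans_array <- function(coef_rest, coef_active, Z) {
  p_ra <- stats::plogis(drop(Z %*% coef_rest))
  p_aa <- stats::plogis(drop(Z %*% coef_active))
  arr <- array(0, c(nrow(Z), 2, 2))
  arr[, 1, 2] <- p_ra; arr[, 1, 1] <- 1 - p_ra
  arr[, 2, 2] <- p_aa; arr[, 2, 1] <- 1 - p_aa
  arr
}

.hmm_emission <- function(x, mu, sigma) {
  cbind(stats::dnorm(x, mu[1], sigma[1]), stats::dnorm(x, mu[2], sigma[2]))
}

# Scaled forward-backward for one segment.
# Returns loglik, gamma (T x 2), xi (T x 2 x 2; xi[t,,] for transition
# t-1 -> t, zero at t = 1).
.hmm_forward_backward <- function(x, Z, mu, sigma, init, coef_rest,
                                  coef_active) {
  Tn <- length(x)
  B <- .hmm_emission(x, mu, sigma)
  A <- .hmm_trans_array(coef_rest, coef_active, Z)
  alpha <- matrix(0, Tn, 2)
  cscale <- numeric(Tn)
  a <- init * B[1, ]
  cscale[1] <- sum(a)
  alpha[1, ] <- a / cscale[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% A[t, , ]) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
  }
  beta <- matrix(0, Tn, 2)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- (A[t + 1, , ] %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- array(0, c(Tn, 2, 2))
  if (Tn > 1) {
    for (t in 2:Tn) {
      m <- (alpha[t - 1, ] %o% (B[t, ] * beta[t, ])) * A[t, , ] / cscale[t]
      xi[t, , ] <- m / sum(m)
    }
  }
  list(loglik = sum(log(cscale)), gamma = gamma, xi = xi)
}

# Weighted logistic regression for one origin state's transition
# coefficients; falls back to the previous coefficients on failure.
.hmm_update_trans <- function(Z, w_active, w_rest, prev) {
  w <- c(w_active, w_rest)
  if (sum(w) < 1e-8) return(prev)
  ZZ <- rbind(Z, Z)
  yy <- c(rep(1, nrow(Z)), rep(0, nrow(Z)))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(ZZ, yy, weights = w,
                                    family = stats::quasibinomial())),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(fit$coefficients)) return(prev)
  co <- fit$coefficients
  co[abs(co) > 25] <- sign(co[abs(co) > 25]) * 25  # separation guard
  co
}

#' Fit a two-state covariate-transition HMM to an activity series
#'
#' @param series Activity series from [build_activity_series()] (or
#'   [simulate_hmm_series()]): needs `value, hss_sin, hss_cos, segment_id`.
#' @param restarts Number of seeded initialisations; the best final
#'   likelihood wins (default 10).
#' @param seed Integer seed controlling the restart jitter.
#' @param tol EM stopping tolerance on the log-likelihood increase
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @return An object of class `hmm_fit`: `state_means` and `state_sds`
#'   (named rest/active, with `mu_active > mu_rest`), `init_prob`,
#'   `trans_coef` (list `rest`, `active`; each `(alpha, beta_sin,
#'   beta_cos)` on the logit of *next state is active*), `log_likelihood`,
#'   `loglik_trace`, `decoded_states` (Viterbi), `n_iters`, `converged`.
#' @export
fit_hmm <- function(series, restarts = 10, seed = 1L, tol = 1e-8,
                    max_iter = 500) {
  x <- series$value
  if (length(x) < 48) stop("need >= 48 observed hours", call. = FALSE)
  Z <- cbind(1, series$hss_sin, series$hss_cos)
  segs <- split(seq_along(x), series$segment_id)
  set.seed(seed)

  # deterministic 2-means-style split for the base initialisation
  med <- stats::median(x)
  lo <- x[x <= med]; hi <- x[x > med]
  base_mu <- c(mean(lo), mean(hi))
  base_sd <- c(max(stats::sd(lo), 1e-3), max(stats::sd(hi), 1e-3))
  spread <- max(diff(base_mu), 1e-3)

  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- base_mu + if (r == 1) 0 else stats::rnorm(2, 0, 0.3 * spread)
    sigma <- base_sd * if (r == 1) 1 else exp(stats::rnorm(2, 0, 0.2))
    init <- c(0.5, 0.5)
    coef_rest <- c(0, 0, 0)
    coef_active <- c(0, 0, 0)
    ll_prev <- -Inf
    trace <- numeric(0)
    converged <- FALSE
    ok <- TRUE
    for (iter in seq_len(max_iter)) {
      ll <- 0
      g_acc <- matrix(0, length(x), 2)
      xa_acc <- matrix(0, length(x), 2)  # xi mass into active by origin
      xr_acc <- matrix(0, length(x), 2)  # xi mass into rest by origin
      first_g <- matrix(0, length(segs), 2)
      tmask <- logical(length(x))
      for (si in seq_along(segs)) {
        idx <- segs[[si]]
        fb <- tryCatch(
          .hmm_forward_backward(x[idx], Z[idx, , drop = FALSE], mu, sigma,
                                init, coef_rest, coef_active),
          error = function(e) NULL
        )
        if (is.null(fb) || !is.finite(fb$loglik)) { ok <- FALSE; break }
        ll <- ll + fb$loglik
        g_acc[idx, ] <- fb$gamma
        first_g[si, ] <- fb$gamma[1, ]
        if (length(idx) > 1) {
          tt <- idx[-1]
          tmask[tt] <- TRUE
          xa_acc[tt, ] <- fb$xi[-1, , 2]
          xr_acc[tt, ] <- fb$xi[-1, , 1]
        }
      }
      if (!ok) break
      trace <- c(trace, ll)
      # M-step
      wsum <- colSums(g_acc)
      mu_new <- colSums(g_acc * x) / wsum
      sd_new <- sqrt(colSums(g_acc * (outer(x, mu_new, "-")^2)) / wsum)
      sd_new <- pmax(sd_new, 1e-4)
      init_new <- colMeans(first_g)
      Zt <- Z[tmask, , drop = FALSE]
      coef_rest <- .hmm_update_trans(Zt, xa_acc[tmask, 1], xr_acc[tmask, 1],
                                     coef_rest)
      coef_active <- .hmm_update_trans(Zt, xa_acc[tmask, 2], xr_acc[tmask, 2],
                                       coef_active)
      mu <- mu_new; sigma <- sd_new; init <- init_new
      if (is.finite(ll_prev) && ll - ll_prev < tol * (1 + abs(ll))) {
        converged <- TRUE
        ll_prev <- ll
        break
      }
      ll_prev <- ll
    }
    if (!ok || !is.finite(ll_prev)) next
    if (is.null(best) || ll_prev > best$log_likelihood) {
      best <- list(mu = mu, sigma = sigma, init = init,
                   coef_rest = coef_rest, coef_active = coef_active,
                   log_likelihood = ll_prev, loglik_trace = trace,
                   n_iters = length(trace), converged = converged)
    }
  }
  if (is.null(best)) stop("all HMM restarts failed (non-finite likelihood)",
                          call. = FALSE)
  # label convention: state 2 = active = larger mean
  if (best$mu[1] > best$mu[2]) {
    best$mu <- rev(best$mu); best$sigma <- rev(best$sigma)
    best$init <- rev(best$init)
    tmp <- best$coef_rest
    best$coef_rest <- -best$coef_active
    best$coef_active <- -tmp
  }
  fit <- structure(list(
    state_means = c(rest = best$mu[1], active = best$mu[2]),
    state_sds = c(rest = best$sigma[1], active = best$sigma[2]),
    init_prob = c(rest = best$init[1], active = best$init[2]),
    trans_coef = list(
      rest = stats::setNames(best$coef_rest, c("alpha", "beta_sin", "beta_cos")),
      active = stats::setNames(best$coef_active, c("alpha", "beta_sin", "beta_cos"))
    ),
    log_likelihood = best$log_likelihood,
    loglik_trace = best$loglik_trace,
    n_iters = best$n_iters, converged = best$converged
  ), class = "hmm_fit")
  fit$decoded_states <- decode_states(fit, series)
  fit
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("Two-state covariate-transition HMM\n")
  cat(sprintf("  rest:   mean %.3f sd %.3f\n", x$state_means["rest"],
              x$state_sds["rest"]))
  cat(sprintf("  active: mean %.3f sd %.3f\n", x$state_means["active"],
              x$state_sds["active"]))
  cat(sprintf("  logLik %.2f after %d EM iterations (%s)\n",
              x$log_likelihood, x$n_iters,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}

#' Forward log-likelihood of a parameter set on a series
#'
#' Exposed separately so the likelihood can be checked against exhaustive
#' path enumeration on short series.
#'
#' @param params A list or `hmm_fit` with `state_means`, `state_sds`,
#'   `init_prob`, `trans_coef`.
#' @param series Activity series (needs `value, hss_sin, hss_cos,
#'   segment_id`).
#' @return The total log-likelihood across segments.
#' @export
hmm_loglik <- function(params, series) {
  x <- series$value
  Z <- cbind(1, series$hss_sin, series$hss_cos)
  ll <- 0
  for (idx in split(seq_along(x), series$segment_id)) {
    fb <- .hmm_forward_backward(
      x[idx], Z[idx, , drop = FALSE],
      unname(params$state_means), unname(params$state_sds),
      unname(params$init_prob), unname(params$trans_coef$rest),
      unname(params$trans_coef$active))
    ll <- ll + fb$loglik
  }
  ll
}

#' Viterbi decoding of the most probable state path
#'
#' Global most-probable path per contiguity segment, using the per-hour
#' transition matrices implied by the fit's coefficients and the series'
#' sine/cosine covariates.
#'
#' @param fit An `hmm_fit` (or compatible parameter list).
#' @param series Activity series.
#' @return Character vector (`"rest"`/`"active"`), one entry per series row.
#' @export
decode_states <- function(fit, series) {
  x <- series$value
  Z <- cbind(1, series$hss_sin, series$hss_cos)
  out <- character(length(x))
  for (idx in split(seq_along(x), series$segment_id)) {
    xi <- x[idx]
    Tn <- length(xi)
    B <- log(.hmm_emission(xi, unname(fit$state_means),
                           unname(fit$state_sds)))
    A <- log(.hmm_trans_array(unname(fit$trans_coef$rest),
                              unname(fit$trans_coef$active),
                              Z[idx, , drop = FALSE]))
    delta <- matrix(-Inf, Tn, 2)
    psi <- matrix(0L, Tn, 2)
    delta[1, ] <- log(unname(fit$init_prob)) + B[1, ]
    if (Tn > 1) {
      for (t in 2:Tn) {
        for (j in 1:2) {
          cand <- delta[t - 1, ] + A[t, , j]
          psi[t, j] <- which.max(cand)
          delta[t, j] <- cand[psi[t, j]] + B[t, j]
        }
      }
    }
    path <- integer(Tn)
    path[Tn] <- which.max(delta[Tn, ])
    if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
    out[idx] <- c("rest", "active")[path]
  }
  out
}

#' Nightly state-vs-condition trends
#'
#' Restricts decoded hours to night (between sunset and the next sunrise at
#' the release site) and fits a univariate logistic regression of state
#' (active = 1) on each of date, hours since sunset, wind speed, and
#' temperature.
#'
#' @param states Decoded states (character, per series row).
#' @param series The matching activity series (needs `hour, hss,
#'   wind_speed, temperature`).
#' @param lat,lon Release coordinates for the night filter.
#' @param night_only Apply the night filter (default TRUE).
#' @return A data.frame `covariate, slope, intercept, n, degenerate`;
#'   `degenerate` flags an all-one-state input (coefficients `NA`).
#' @export
state_condition_trends <- function(states, series, lat, lon,
                                   night_only = TRUE) {
  keep <- rep(TRUE, nrow(series))
  if (night_only) keep <- is_night(series$hour + 1800, lat, lon)
  y <- as.integer(states[keep] == "active")
  covs <- list(
    date = as.numeric(as.Date(series$hour[keep], tz = "UTC")),
    hours_since_sunset = series$hss[keep],
    wind_speed = series$wind_speed[keep],
    temperature = series$temperature[keep]
  )
  out <- lapply(names(covs), function(v) {
    xx <- covs[[v]]
    okrows <- !is.na(xx)
    if (length(unique(y[okrows])) < 2) {
      return(data.frame(covariate = v, slope = NA_real_,
                        intercept = NA_real_, n = sum(okrows),
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    g <- suppressWarnings(stats::glm(y[okrows] ~ xx[okrows],
                                     family = stats::binomial()))
    data.frame(covariate = v, slope = unname(stats::coef(g)[2]),
               intercept = unname(stats::coef(g)[1]), n = sum(okrows),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
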