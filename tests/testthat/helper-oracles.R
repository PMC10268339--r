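# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: solar position via the Michalsky almanac
# algorithm with numerical root finding, HMM quantities via exhaustive path
# enumeration.

# --- Solar elevation (Michalsky 1988, Astronomical Almanac) --------------
# Accurate to ~0.01 degrees; entirely different route from the closed-form
# sunset equation used in the package.
oracle_solar_elevation_deg <- function(t, lat, lon) {
  # days from J2000.0
  jd <- as.numeric(t) / 86400 + 2440587.5
  n <- jd - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360          # mean longitude
  g <- ((357.528 + 0.9856003 * n) %% 360) * pi / 180  # mean anomaly
  lambda <- (L + 1.915 * sin(g) + 0.020 * sin(2 * g)) * pi / 180
  eps <- (23.439 - 0.0000004 * n) * pi / 180     # obliquity
  alpha <- atan2(cos(eps) * sin(lambda), cos(lambda))  # right ascension
  delta <- asin(sin(eps) * sin(lambda))          # declination
  gmst <- (6.697375 + 0.0657098242 * n +
             (as.numeric(t) / 3600) %% 24) %% 24 # Greenwich mean sidereal
  lmst <- ((gmst + lon / 15) %% 24) * 15 * pi / 180
  ha <- lmst - alpha                              # hour angle
  el <- asin(sin(delta) * sin(lat * pi / 180) +
               cos(delta) * cos(lat * pi / 180) * cos(ha))
  el * 180 / pi
}

# Sunset instant by bisection on the oracle elevation (zenith 90.833 deg),
# searching the afternoon/evening of the given UTC-ish local date.
oracle_sunset_utc <- function(date, lat, lon) {
  noon_utc <- as.POSIXct(paste(date, "12:00:00"), tz = "UTC") - lon / 15 * 3600
  f <- function(s) {
    oracle_solar_elevation_deg(noon_utc + s, lat, lon) + 0.833
  }
  r <- stats::uniroot(f, c(0, 12 * 3600), tol = 1)
  noon_utc + r$root
}

# --- HMM brute force ------------------------------------------------------
# Likelihood and best path by explicit enumeration of all 2^T state
# sequences, using the same parameter convention as the package (state 2 =
# active; transition into time t uses covariates at t; P(active next) =
# plogis(alpha + bsin * sin_t + bcos * cos_t) for the origin state).
oracle_hmm_enumerate <- function(params, series) {
  x <- series$value
  Tn <- length(x)
  stopifnot(Tn <= 12)
  mu <- unname(params$state_means)
  sdv <- unname(params$state_sds)
  init <- unname(params$init_prob)
  cr <- unname(params$trans_coef$rest)
  ca <- unname(params$trans_coef$active)
  p_act <- function(co, t) {
    stats::plogis(co[1] + co[2] * series$hss_sin[t] + co[3] * series$hss_cos[t])
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  lik <- apply(paths, 1, function(s) {
    p <- init[s[1]] * stats::dnorm(x[1], mu[s[1]], sdv[s[1]])
    if (Tn > 1) {
      for (t in 2:Tn) {
        co <- if (s[t - 1] == 1) cr else ca
        pa <- p_act(co, t)
        p <- p * (if (s[t] == 2) pa else 1 - pa) *
          stats::dnorm(x[t], mu[s[t]], sdv[s[t]])
      }
    }
    p
  })
  list(loglik = log(sum(lik)),
       best_path = c("rest", "active")[paths[which.max(lik), ]])
}

# Random parameter set + short series for oracle comparisons.
random_hmm_case <- function(seed, Tn = 8) {
  set.seed(seed)
  hss <- runif(Tn, 0, 24)
  cyc_s <- sin(2 * pi * hss / 24)
  cyc_c <- cos(2 * pi * hss / 24)
  params <- list(
    state_means = c(rest = runif(1, 0.1, 0.5), active = runif(1, 0.8, 1.5)),
    state_sds = c(rest = runif(1, 0.05, 0.3), active = runif(1, 0.2, 0.5)),
    init_prob = {
      p <- runif(1, 0.2, 0.8)
      c(rest = p, active = 1 - p)
    },
    trans_coef = list(rest = rnorm(3, 0, 1.5), active = rnorm(3, 0, 1.5))
  )
  series <- data.frame(
    tag_id = "o", hour = as.POSIXct("2021-09-01", tz = "UTC") + 3600 * (1:Tn),
    value = rnorm(Tn, sample(c(0.3, 1), Tn, replace = TRUE), 0.3),
    hss_sin = cyc_s, hss_cos = cyc_c, segment_id = 1L,
    stringsAsFactors = FALSE
  )
  list(params = params, series = series)
}
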