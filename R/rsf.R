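# Random-intercept logistic regression for the use-availability design,
# maximised by adaptive Gauss-Hermite quadrature (the random intercept is
# one-dimensional, so the marginal likelihood is a product of 1-D
# integrals). Standard errors come from the inverse observed information at
# the optimum. The all-subsets search ranks every additive combination of
# the candidate covariates by AICc.

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via Golub-Welsch.
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

.log1pexp <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

# Marginal negative log-likelihood of the random-intercept logit, with its
# gradient (the posterior-expected score, computed from the same quadrature
# pass). X: model matrix, y: 0/1, gid: integer group index 1..G.
# theta = c(beta, log_sd) unless fix_sd is given (then theta = beta).
# `cache` (an environment) warm-starts the inner Newton across calls.
.mixed_logit_eval <- function(theta, X, y, gid, G, gh, fix_sd = NULL,
                              cache = NULL) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sd_b <- if (is.null(fix_sd)) exp(theta[p + 1]) else fix_sd
  eta0 <- drop(X %*% beta)
  if (sd_b < 1e-10) {
    mu <- 1 / (1 + exp(-eta0))
    out <- list(nll = -sum(y * eta0 - .log1pexp(eta0)),
                grad = -drop(crossprod(X, y - mu)))
    if (is.null(fix_sd)) out$grad <- c(out$grad, 0)
    return(out)
  }
  # inner Newton for the G conditional modes (vectorised across groups)
  inv_var <- 1 / sd_b^2
  b <- if (!is.null(cache) && !is.null(cache$b)) cache$b else numeric(G)
  for (it in 1:50) {
    eta <- eta0 + b[gid]
    mu <- 1 / (1 + exp(-eta))
    gw <- rowsum(cbind(y - mu, mu * (1 - mu)), gid, reorder = TRUE)
    grad <- gw[, 1] - b * inv_var
    W <- gw[, 2] + inv_var
    step <- grad / W
    # damp the step and clamp the modes: with a near-flat prior (huge sd)
    # and a saturated group the undamped Newton oscillates
    step <- pmin(pmax(step, -10), 10)
    b <- pmin(pmax(b + step, -50), 50)
    if (max(abs(grad)) < 1e-8) break
  }
  if (!is.null(cache)) cache$b <- b
  eta <- eta0 + b[gid]
  mu <- 1 / (1 + exp(-eta))
  W <- as.numeric(rowsum(mu * (1 - mu), gid, reorder = TRUE)) + inv_var
  s <- 1 / sqrt(W)
  # adaptive quadrature: all nodes at once (n x J linear predictors,
  # group-summed with a single rowsum); log-priors written out inline
  ldnorm <- function(v) -0.918938533204673 - log(sd_b) - 0.5 * v * v * inv_var
  nodes <- gh$nodes
  Bmat <- b + sqrt(2) * outer(s, nodes)                   # G x J
  Emat <- eta0 + Bmat[gid, , drop = FALSE]                # n x J
  Hmat <- rowsum(y * Emat - .log1pexp(Emat), gid, reorder = TRUE) +
    ldnorm(Bmat)                                          # G x J
  h_mode <- as.numeric(rowsum(y * eta - .log1pexp(eta), gid, reorder = TRUE)) +
    ldnorm(b)
  K <- exp(Hmat - h_mode + rep(nodes^2, each = G)) *
    rep(gh$weights, each = G)                             # G x J kernel
  acc <- rowSums(K)
  ll <- sum(h_mode + log(sqrt(2) * s) + log(acc))
  # gradient = negative posterior-expected score
  Wn <- K / acc                                           # posterior weights
  MU <- 1 / (1 + exp(-Emat))
  R <- rowSums((y - MU) * Wn[gid, , drop = FALSE])        # per-row residual
  grad <- -drop(crossprod(X, R))
  if (is.null(fix_sd)) {
    grad_ls <- -sum(Wn * ((Bmat / sd_b)^2 - 1))
    grad <- c(grad, grad_ls)
  }
  list(nll = -ll, grad = grad)
}

.mixed_logit_nll <- function(theta, X, y, gid, G, gh, fix_sd = NULL,
                             cache = NULL) {
  .mixed_logit_eval(theta, X, y, gid, G, gh, fix_sd, cache)$nll
}

#' Fit the random-intercept logistic selection model
#'
#' Logit model of used (1) vs available (0) instances with the requested
#' fixed effects plus a per-tag Gaussian random intercept, whose marginal
#' likelihood is integrated by adaptive Gauss-Hermite quadrature. With
#' `fix_sd = 0` the model degenerates to ordinary logistic regression.
#'
#' @param rows Use-availability table from [attach_covariates()] (columns
#'   `used`, `tag_id`, and the covariates).
#' @param variable_subset Character vector of covariate columns entering as
#'   fixed effects (an intercept is always included).
#' @param nagq Number of quadrature nodes (default 15).
#' @param fix_sd Optionally pin the random-intercept SD (e.g. 0); `NULL`
#'   (default) estimates it.
#' @param start Optional warm-start parameter vector `c(beta, log_sd)` on
#'   the original covariate scale.
#' @param include_aicc Compute AICc (default TRUE).
#' @param compute_se Compute the observed-information standard errors
#'   (default TRUE; the all-subsets search turns this off for speed and
#'   restores it on the ranked models it returns).
#' @return An object of class `rsf_fit`: `variable_subset`, `beta`, `se`,
#'   `z`, `p` (Wald, two-sided normal), `vcov` (fixed effects),
#'   `random_intercept_sd`, `log_likelihood`, `aicc`, `npar`, `n_used`,
#'   `n_available`, `converged`.
#' @export
fit_mixed_logit <- function(rows, variable_subset, nagq = 15, fix_sd = NULL,
                            start = NULL, include_aicc = TRUE,
                            compute_se = TRUE) {
  if (!all(c("used", "tag_id") %in% names(rows))) {
    stop("rows must contain 'used' and 'tag_id'", call. = FALSE)
  }
  missing_vars <- setdiff(variable_subset, names(rows))
  if (length(missing_vars)) {
    stop("covariates not in rows: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(rows$tag_id)) < 2 && is.null(fix_sd)) {
    stop("need >= 2 tags to estimate a random intercept", call. = FALSE)
  }
  y <- rows$used
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2) {
    stop("need both used and available rows", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(rows[, variable_subset, drop = FALSE]))
  if (anyNA(X)) stop("missing covariate values in fitted rows", call. = FALSE)
  gid <- as.integer(factor(rows$tag_id))
  G <- max(gid)
  gh <- .gauss_hermite(nagq)
  p <- ncol(X)

  # optimise on a standardised covariate scale for conditioning; map back
  # afterwards (T: original beta = T %*% standardised beta)
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  Tmat <- diag(1 / scl, p)
  Tmat[1, ] <- c(1, -ctr[-1] / scl[-1])
  to_std <- function(beta) c(beta[1] + sum(beta[-1] * ctr[-1]), beta[-1] * scl[-1])

  # start from the ordinary logistic fit (or a caller-supplied warm start,
  # given on the original scale)
  if (is.null(start)) {
    g0 <- suppressWarnings(stats::glm.fit(Xs, y, family = stats::binomial()))
    start_s <- c(g0$coefficients, if (is.null(fix_sd)) log(0.5))
    start_s[is.na(start_s)] <- 0
  } else {
    stopifnot(length(start) == p + if (is.null(fix_sd)) 1L else 0L)
    start_s <- c(to_std(start[seq_len(p)]),
                 if (is.null(fix_sd)) start[p + 1])
  }

  cache <- new.env(parent = emptyenv())
  eval_at <- function(th) {
    if (!is.null(cache$theta) && identical(cache$theta, th)) return(cache$res)
    res <- .mixed_logit_eval(th, Xs, y, gid, G, gh, fix_sd, cache)
    cache$theta <- th
    cache$res <- res
    res
  }
  nll_s <- function(th) eval_at(th)$nll
  grad_s <- function(th) eval_at(th)$grad
  opt <- stats::optim(start_s, nll_s, grad_s, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-11))
  grad <- .num_grad(nll_s, opt$par)
  if (opt$convergence != 0 && sqrt(sum(grad^2)) > 1e-3) {
    stop(sprintf("mixed logit did not converge (gradient norm %.3g)",
                 sqrt(sum(grad^2))), call. = FALSE)
  }
  # on the standardised scale a unit move is ~1 SD of the covariate, so a
  # huge coefficient really does indicate (quasi-)separation
  if (any(abs(opt$par[2:p]) > 30)) {
    stop("complete separation suspected (diverging coefficients)",
         call. = FALSE)
  }
  beta <- drop(Tmat %*% opt$par[seq_len(p)])
  names(beta) <- colnames(X)
  if (compute_se) {
    H <- stats::optimHess(opt$par, nll_s)
    Vs <- tryCatch(solve(H), error = function(e) {
      matrix(NA_real_, nrow(H), ncol(H))
    })
    V <- Tmat %*% Vs[seq_len(p), seq_len(p), drop = FALSE] %*% t(Tmat)
    se <- sqrt(pmax(diag(V), 0))
  } else {
    V <- matrix(NA_real_, p, p)
    se <- rep(NA_real_, p)
  }
  names(se) <- colnames(X)
  z <- beta / se
  pval <- 2 * stats::pnorm(-abs(z))
  sd_b <- if (is.null(fix_sd)) unname(exp(opt$par[p + 1])) else fix_sd
  ll <- -opt$value
  k <- p + if (is.null(fix_sd)) 1L else 0L
  n <- nrow(rows)
  aicc <- if (include_aicc && n - k - 1 > 0) {
    -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else {
    NA_real_
  }
  structure(list(
    variable_subset = variable_subset, beta = beta, se = se, z = z, p = pval,
    vcov = V,
    random_intercept_sd = sd_b, log_likelihood = ll, aicc = aicc, npar = k,
    n_used = sum(y == 1), n_available = sum(y == 0),
    n = n, converged = opt$convergence == 0,
    par = c(beta, if (is.null(fix_sd)) opt$par[p + 1])
  ), class = "rsf_fit")
}

.num_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0.0)
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat("Random-intercept logistic selection model\n")
  cat(sprintf("  %d used / %d available rows, %s\n", x$n_used, x$n_available,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    z = round(x$z, 2), p = signif(x$p, 3))
  print(tab)
  cat(sprintf("  random-intercept SD %.3f | logLik %.2f | AICc %.2f\n",
              x$random_intercept_sd, x$log_likelihood, x$aicc))
  invisible(x)
}

#' All-subsets AICc model selection
#'
#' Fits every additive subset of `candidate_vars` (2^length models), each
#' also containing `always_in` and the random intercept, and ranks by AICc
#' with `k = n_fixed_effects + 1` (the random-intercept SD) and `n` the row
#' count. Models with `n <= k + 1` are infeasible and excluded with a
#' warning. The full-model fit warm-starts every subset.
#'
#' @param rows Use-availability table.
#' @param candidate_vars Candidate covariates (default
#'   [candidate_covariates()], the ten atmospheric variables).
#' @param always_in Covariates held in every model (default hours since
#'   sunset).
#' @param nagq Quadrature nodes (default 15).
#' @return A list of class `rsf_dredge`: `table` (one row per model, with
#'   `model_id, k, log_likelihood, aicc, delta_aicc, variables`, sorted by
#'   AICc), `fits` (list of `rsf_fit` in the same order), `retained`
#'   (logical, `delta_aicc < 2`), and `n_models`.
#' @export
dredge_aicc <- function(rows, candidate_vars = candidate_covariates(),
                        always_in = "hours_since_sunset", nagq = 15) {
  if (length(candidate_vars) == 0) stop("empty candidate set", call. = FALSE)
  m <- length(candidate_vars)
  full <- fit_mixed_logit(rows, c(always_in, candidate_vars), nagq = nagq)
  full_par <- full$par
  full_names <- c("(Intercept)", always_in, candidate_vars)
  n_models <- 2^m
  fits <- vector("list", n_models)
  feasible <- logical(n_models)
  for (id in seq_len(n_models)) {
    bits <- as.logical(bitwAnd(id - 1L, bitwShiftL(1L, seq_len(m) - 1L)))
    vars <- c(always_in, candidate_vars[bits])
    k <- length(vars) + 2L  # + intercept + random-intercept SD
    if (nrow(rows) <= k + 1) {
      feasible[id] <- FALSE
      next
    }
    keep <- match(c("(Intercept)", vars), full_names)
    start <- c(full_par[keep], full_par[length(full_par)])
    fits[[id]] <- fit_mixed_logit(rows, vars, nagq = nagq, start = start,
                                  compute_se = FALSE)
    feasible[id] <- TRUE
  }
  if (!all(feasible)) {
    warning(sum(!feasible), " model(s) infeasible (n <= k + 1); excluded")
  }
  fits <- fits[feasible]
  tab <- data.frame(
    model_id = seq_along(fits),
    k = vapply(fits, function(f) f$npar, 0L),
    log_likelihood = vapply(fits, function(f) f$log_likelihood, 0.0),
    aicc = vapply(fits, function(f) f$aicc, 0.0),
    variables = vapply(fits, function(f)
      paste(f$variable_subset, collapse = "+"), ""),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  fits <- fits[ord]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  # restore standard errors on the competing (< 2 dAICc) models
  for (i in which(tab$delta_aicc < 2)) {
    fits[[i]] <- fit_mixed_logit(rows, fits[[i]]$variable_subset,
                                 nagq = nagq, start = fits[[i]]$par)
  }
  structure(list(table = tab, fits = fits,
                 retained = tab$delta_aicc < 2, n_models = nrow(tab)),
            class = "rsf_dredge")
}

#' @export
print.rsf_dredge <- function(x, ...) {
  cat(sprintf("All-subsets AICc selection: %d models, %d within 2 dAICc\n",
              x$n_models, sum(x$retained)))
  print(utils::head(x$table[, c("variables", "k", "aicc", "delta_aicc")], 5))
  invisible(x)
}

#' Marginal-effect curve for one covariate
#'
#' Predicted relative probability of use over the observed range of one
#' covariate, holding the other covariates at their sample means and the
#' random intercept at zero, with a 95% interval from the delta method on
#' the linear predictor (computed on the logit scale, then inverse-logit
#' transformed, so the band brackets the estimate everywhere).
#'
#' @param fit An `rsf_fit`.
#' @param rows The table the model was fitted to.
#' @param variable A covariate in the fitted subset.
#' @param grid_size Number of evaluation points (default 100).
#' @return A data.frame `value, prob, lower95, upper95`.
#' @export
marginal_effects <- function(fit, rows, variable, grid_size = 100) {
  if (!variable %in% fit$variable_subset) {
    stop("variable not in the fitted model: ", variable, call. = FALSE)
  }
  vars <- fit$variable_subset
  grid <- seq(min(rows[[variable]]), max(rows[[variable]]),
              length.out = grid_size)
  xbar <- vapply(vars, function(v) mean(rows[[v]]), 0.0)
  X <- matrix(rep(c(1, xbar), each = grid_size), nrow = grid_size)
  colnames(X) <- c("(Intercept)", vars)
  X[, variable] <- grid
  eta <- drop(X %*% fit$beta)
  se_eta <- sqrt(pmax(rowSums((X %*% fit$vcov) * X), 0))
  data.frame(value = grid,
             prob = stats::plogis(eta),
             lower95 = stats::plogis(eta - 1.96 * se_eta),
             upper95 = stats::plogis(eta + 1.96 * se_eta))
}
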