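# Data-augmented Metropolis-within-Gibbs sampler for the single-season
# occupancy model:
#
#   z_i   ~ Bernoulli(psi_i),        logit(psi_i)  = X_psi[i, ] %*% beta
#   y_ij  ~ Bernoulli(z_i * p_ij),   logit(p_ij)   = X_p[ij, ] %*% alpha + eps_i
#   eps_i ~ Normal(0, tau.alpha0),   sd.alpha0 = sqrt(tau.alpha0)
#
# One sweep: (a) exact Gibbs draw of every latent z_i; (b) random-walk
# Metropolis on each occupancy coefficient; (c) on each detection
# coefficient; (d) on each site random effect (vectorized, the effects are
# conditionally independent); (e) on the random-effect sd against its
# uniform prior. Proposal scales adapt toward a 20-45% acceptance rate
# during burn-in only, so the post-burn-in sweep leaves the joint posterior
# invariant.

# Bernoulli log-likelihood on the logit scale, clamped for stability.
bern_ll <- function(y, eta) {
  p <- inv_logit(eta)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

# per-observation Bernoulli log-density (same clamping), for site sums
bern_ll_vec <- function(y, eta) {
  p <- inv_logit(eta)
  y * log(p) + (1 - y) * log1p(-p)
}

#' Full conditional probability of site occupancy
#'
#' Probability that a site is occupied given its detection history, its
#' occupancy probability and its per-visit detection probabilities. A site
#' with at least one detection is occupied with probability 1; an all-zero
#' history yields the Bayes-rule posterior
#' `psi * prod(1 - p) / (psi * prod(1 - p) + (1 - psi))`.
#'
#' @param psi occupancy probability of the site (scalar in `[0, 1]`).
#' @param p per-visit detection probabilities (same length as `y`).
#' @param y 0/1 detection history.
#' @return `P(z = 1 | y, psi, p)`.
#' @examples
#' conditional_z_probability(0.5, c(0.5, 0.5), c(0, 0)) # 0.2
#' @export
conditional_z_probability <- function(psi, p, y) {
  if (length(p) != length(y))
    stop_occu("p and y must have the same length", class = "occu_bad_input")
  if (psi < 0 || psi > 1 || any(p < 0) || any(p > 1))
    stop_occu("probabilities must lie in [0, 1]", class = "occu_numerical_domain")
  if (any(y == 1)) return(1)
  num <- psi * prod(1 - p)
  num / (num + (1 - psi))
}

# design matrices for a dataset under a model specification
build_model_matrices <- function(data, spec) {
  stopifnot(inherits(data, "occu_data"), inherits(spec, "occu_model_spec"))
  if (!data$standardized)
    warning("fitting on non-standardized covariates; see prepare_occu_data()")
  site_idx <- visit_site_index(data)
  X_psi <- cbind("(Intercept)" = rep(1, n_sites(data)))
  for (t in spec$occupancy_terms)
    X_psi <- cbind(X_psi, data$sites[[t]])
  colnames(X_psi) <- c("(Intercept)", spec$occupancy_terms)
  X_p <- cbind("(Intercept)" = rep(1, nrow(data$visits)))
  for (t in spec$detection_terms) {
    col <- if (t == "temperature2") data$visits$temperature^2
           else if (t %in% site_covariate_names()) data$sites[[t]][site_idx]
           else data$visits[[t]]
    X_p <- cbind(X_p, col)
  }
  colnames(X_p) <- c("(Intercept)", spec$detection_terms)
  list(X_psi = X_psi, X_p = X_p, site_idx = site_idx,
       y = data$visits$y, obs_z = observed_occupancy(data))
}

#' Complete-data log-likelihood of the occupancy model
#'
#' Sum over sites of the Bernoulli log-probability of the latent state plus,
#' for occupied sites only, the Bernoulli log-probability of each visit's
#' detection outcome. Unoccupied sites contribute `log(1 - psi_i)` alone
#' (their all-zero histories are structural).
#'
#' @param data an [occu_data()] object (standardized).
#' @param spec an [model_spec()].
#' @param beta occupancy coefficients (intercept first, then
#'   `spec$occupancy_terms` in order).
#' @param alpha detection coefficients (intercept first, then
#'   `spec$detection_terms` in order).
#' @param z 0/1 latent occupancy states, one per site.
#' @param eps site random effects added to the detection linear predictor
#'   (default all zero).
#' @return scalar log-likelihood.
#' @export
occu_loglik <- function(data, spec, beta, alpha, z, eps = NULL) {
  mats <- build_model_matrices(data, spec)
  if (is.null(eps)) eps <- numeric(n_sites(data))
  if (length(beta) != ncol(mats$X_psi) || length(alpha) != ncol(mats$X_p))
    stop_occu("coefficient length does not match model terms",
              class = "occu_bad_input")
  if (any(!is.finite(beta)) || any(!is.finite(alpha)) || any(!is.finite(eps)))
    stop_occu("non-finite parameter value", class = "occu_numerical_domain")
  eta_psi <- drop(mats$X_psi %*% beta)
  eta_p <- drop(mats$X_p %*% alpha) + eps[mats$site_idx]
  occ <- z[mats$site_idx] == 1
  bern_ll(z, eta_psi) + bern_ll(mats$y[occ], eta_p[occ])
}

#' Initialize the sampler state
#'
#' Latent states start at the observed detection indicator (the only value
#' with positive support at sites with detections), coefficients at
#' independent Normal(0, 1) draws for over-dispersed chain starts, random
#' effects at 0 and their sd at 1.
#'
#' @param data an [occu_data()] object.
#' @param spec an [model_spec()].
#' @param seed optional integer seed applied before drawing the start.
#' @param prior_only if `TRUE` the likelihood is replaced by a constant, so
#'   the sampler targets the prior (used to validate the Metropolis
#'   machinery).
#' @param overdisperse draw Normal(0, 1) coefficient starts (`TRUE`) or
#'   start exactly at 0 (`FALSE`).
#' @return An `occu_mcmc_state` object, advanced by [mcmc_step()].
#' @export
mcmc_init <- function(data, spec, seed = NULL, prior_only = FALSE,
                      overdisperse = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  mats <- build_model_matrices(data, spec)
  kb <- ncol(mats$X_psi)
  ka <- ncol(mats$X_p)
  n <- n_sites(data)
  beta <- if (overdisperse) stats::rnorm(kb) else numeric(kb)
  alpha <- if (overdisperse) stats::rnorm(ka) else numeric(ka)
  eps <- numeric(n)
  sd0 <- 1
  z <- mats$obs_z
  state <- list(
    mats = mats, spec = spec, prior_only = isTRUE(prior_only),
    beta = beta, alpha = alpha, eps = eps, sd0 = sd0, z = z,
    eta_psi = drop(mats$X_psi %*% beta),
    eta_p = drop(mats$X_p %*% alpha),
    scales = list(beta = rep(0.5, kb), alpha = rep(0.5, ka),
                  eps = 0.5, sd0 = 0.3),
    acc = list(beta = numeric(kb), alpha = numeric(ka), eps = 0, sd0 = 0),
    window = 0L, iter = 0L
  )
  lp <- state_log_posterior(state)
  if (!is.finite(lp))
    stop_occu("non-finite log posterior at initialization",
              class = "occu_init_error")
  structure(state, class = "occu_mcmc_state")
}

state_log_posterior <- function(state) {
  s <- state
  m <- s$mats
  ll <- 0
  if (!s$prior_only) {
    occ <- s$z[m$site_idx] == 1
    ll <- bern_ll(s$z, s$eta_psi) +
      bern_ll(m$y[occ], s$eta_p[occ] + s$eps[m$site_idx][occ])
  }
  prior_ld <- coef_prior_ld(s$spec)
  lp <- ll +
    sum(vapply(seq_along(s$beta),
               function(k) prior_ld(s$beta[k], k), numeric(1))) +
    sum(vapply(seq_along(s$alpha),
               function(k) prior_ld(s$alpha[k], k), numeric(1)))
  if (s$spec$include_site_random_effect)
    lp <- lp + sum(stats::dnorm(s$eps, 0, s$sd0, log = TRUE)) +
      stats::dunif(s$sd0, 0, s$spec$prior_re_sd_upper, log = TRUE)
  lp
}

# log prior density of one coefficient vector: Logistic(0, 1) on the
# intercept (= Uniform(0,1) on its inverse logit) unless the spec asks for
# normal intercepts; Normal(0, prior_coef_sd) on slopes
coef_prior_ld <- function(spec) {
  sd <- spec$prior_coef_sd
  uniform_intercept <- is.null(spec$intercept_prior) ||
    spec$intercept_prior == "uniform"
  function(value, k) {
    if (k == 1L && uniform_intercept) stats::dlogis(value, 0, 1, log = TRUE)
    else stats::dnorm(value, 0, sd, log = TRUE)
  }
}

# random-walk Metropolis over each coefficient of one block, with
# incremental linear-predictor updates; ll_fun maps eta to a scalar
# log-likelihood, prior_ld(value, k) to the coefficient's log prior
update_coef_block <- function(coefs, eta, X, scales, prior_ld, ll_fun) {
  accepted <- logical(length(coefs))
  ll_cur <- ll_fun(eta)
  for (k in seq_along(coefs)) {
    delta <- scales[k] * stats::rnorm(1)
    bnew <- coefs[k] + delta
    eta_new <- eta + X[, k] * delta
    ll_new <- ll_fun(eta_new)
    logr <- ll_new - ll_cur + prior_ld(bnew, k) - prior_ld(coefs[k], k)
    u <- stats::runif(1)
    if (is.finite(logr) && log(u) < logr) {
      coefs[k] <- bnew
      eta <- eta_new
      ll_cur <- ll_new
      accepted[k] <- TRUE
    }
  }
  list(coefs = coefs, eta = eta, accepted = accepted)
}

#' Advance the sampler by one full sweep
#'
#' Performs the Gibbs update of every latent state, Metropolis updates of
#' all occupancy and detection coefficients, and (when the model includes
#' them) of the site random effects and their standard deviation. With
#' `adapt = TRUE` the proposal scales are retuned every 50 sweeps toward a
#' 20-45% acceptance rate; adaptation must only be used during burn-in.
#'
#' @param state an `occu_mcmc_state` from [mcmc_init()].
#' @param adapt retune proposal scales this sweep?
#' @return The updated state.
#' @export
mcmc_step <- function(state, adapt = FALSE) {
  s <- state
  m <- s$mats
  n <- length(s$z)
  prior_ld <- coef_prior_ld(s$spec)

  # (a) exact full conditional of z
  psi <- inv_logit(s$eta_psi)
  if (s$prior_only) {
    q <- psi
  } else {
    eta_det <- s$eta_p + s$eps[m$site_idx]
    l1mp <- log1p(-inv_logit(eta_det))
    s0 <- drop(rowsum(l1mp, m$site_idx)) # sum of log(1-p) per site
    # log-odds of occupancy for an all-zero history
    q <- 1 / (1 + exp(log1p(-psi) - log(psi) - s0))
  }
  znew <- stats::rbinom(n, 1, q)
  znew[m$obs_z == 1] <- 1L
  s$z <- znew

  # (b) occupancy coefficients
  z <- s$z
  ll_occ <- if (s$prior_only) function(eta) 0 else function(eta) bern_ll(z, eta)
  up <- update_coef_block(s$beta, s$eta_psi, m$X_psi, s$scales$beta,
                          prior_ld, ll_occ)
  s$beta <- up$coefs
  s$eta_psi <- up$eta
  s$acc$beta <- s$acc$beta + up$accepted

  # (c) detection coefficients (likelihood over occupied sites' visits only)
  occ_idx <- which(z[m$site_idx] == 1L)
  y_occ <- m$y[occ_idx]
  eps_occ <- s$eps[m$site_idx][occ_idx]
  ll_det <- if (s$prior_only) function(eta) 0 else
    function(eta) bern_ll(y_occ, eta[occ_idx] + eps_occ)
  up <- update_coef_block(s$alpha, s$eta_p, m$X_p, s$scales$alpha,
                          prior_ld, ll_det)
  s$alpha <- up$coefs
  s$eta_p <- up$eta
  s$acc$alpha <- s$acc$alpha + up$accepted

  if (s$spec$include_site_random_effect) {
    # (d) site random effects: conditionally independent, updated jointly
    eps_new <- s$eps + s$scales$eps * stats::rnorm(n)
    if (s$prior_only) {
      site_diff <- numeric(n)
    } else {
      occ_vis <- z[m$site_idx] == 1L
      d_cur <- bern_ll_vec(m$y, s$eta_p + s$eps[m$site_idx]) * occ_vis
      d_new <- bern_ll_vec(m$y, s$eta_p + eps_new[m$site_idx]) * occ_vis
      site_diff <- drop(rowsum(d_new - d_cur, m$site_idx))
    }
    logr <- site_diff +
      stats::dnorm(eps_new, 0, s$sd0, log = TRUE) -
      stats::dnorm(s$eps, 0, s$sd0, log = TRUE)
    acc <- is.finite(logr) & log(stats::runif(n)) < logr
    s$eps[acc] <- eps_new[acc]
    s$acc$eps <- s$acc$eps + mean(acc)

    # (e) random-effect sd, uniform prior
    sd_new <- s$sd0 + s$scales$sd0 * stats::rnorm(1)
    u <- stats::runif(1) # drawn unconditionally: fixed stream length per sweep
    if (sd_new > 0 && sd_new < s$spec$prior_re_sd_upper) {
      logr <- sum(stats::dnorm(s$eps, 0, sd_new, log = TRUE)) -
        sum(stats::dnorm(s$eps, 0, s$sd0, log = TRUE))
      if (is.finite(logr) && log(u) < logr) {
        s$sd0 <- sd_new
        s$acc$sd0 <- s$acc$sd0 + 1
      }
    }
  }

  s$iter <- s$iter + 1L
  s$window <- s$window + 1L
  if (adapt && s$window >= 50L) {
    retune <- function(scale, rate) {
      ifelse(rate < 0.20, scale * 0.8, ifelse(rate > 0.45, scale * 1.25, scale))
    }
    w <- s$window
    s$scales$beta <- retune(s$scales$beta, s$acc$beta / w)
    s$scales$alpha <- retune(s$scales$alpha, s$acc$alpha / w)
    if (s$spec$include_site_random_effect) {
      s$scales$eps <- retune(s$scales$eps, s$acc$eps / w)
      s$scales$sd0 <- retune(s$scales$sd0, s$acc$sd0 / w)
    }
    s$acc <- list(beta = numeric(length(s$beta)),
                  alpha = numeric(length(s$alpha)), eps = 0, sd0 = 0)
    s$window <- 0L
  }
  s
}

occu_param_names <- function(spec) {
  nm <- c("beta0",
          if (length(spec$occupancy_terms)) paste0("beta_", spec$occupancy_terms),
          "alpha0",
          if (length(spec$detection_terms)) paste0("alpha_", spec$detection_terms))
  if (spec$include_site_random_effect) nm <- c(nm, "sd.alpha0", "tau.alpha0")
  nm
}

#' Fit the occupancy model by MCMC
#'
#' Runs independent chains of the data-augmented Metropolis-within-Gibbs
#' sampler from over-dispersed starting points, discards the burn-in,
#' retains every `thin`-th draw and returns them organized by chain.
#' Proposal-scale adaptation happens only during burn-in, so the retained
#' draws come from a fixed transition kernel whose invariant distribution is
#' the joint posterior. The run is reproducible bit-for-bit from
#' `config$master_seed` (each chain derives its own stream).
#'
#' @param data an [occu_data()] object with standardized covariates.
#' @param spec an [model_spec()].
#' @param config an [chain_config()].
#' @param prior_only replace the likelihood by a constant so the draws
#'   target the prior (validation aid).
#' @return An object of class `occu_draws`: retained draws of all
#'   coefficients (plus `sd.alpha0`/`tau.alpha0` when the random effect is
#'   on), the latent states `z` and random effects `eps` per draw, and the
#'   model/chain metadata.
#' @examples
#' sim <- simulate_study(generator_config(n_sites = 30, seed = 7))
#' fit <- run_occu_mcmc(sim$data, model_spec(),
#'                      chain_config(2, 400, 200, 2, master_seed = 7))
#' fit
#' @export
run_occu_mcmc <- function(data, spec, config, prior_only = FALSE) {
  stopifnot(inherits(config, "occu_chain_config"))
  n_keep <- retained_draws(config, total = FALSE)
  pn <- occu_param_names(spec)
  n <- n_sites(data)
  params <- vector("list", config$n_chains)
  z_draws <- vector("list", config$n_chains)
  eps_draws <- if (spec$include_site_random_effect)
    vector("list", config$n_chains) else NULL
  accept <- vector("list", config$n_chains)

  for (ch in seq_len(config$n_chains)) {
    state <- mcmc_init(data, spec,
                       seed = derive_seed(config$master_seed, 100L + ch),
                       prior_only = prior_only)
    P <- matrix(NA_real_, n_keep, length(pn), dimnames = list(NULL, pn))
    Z <- matrix(NA_integer_, n_keep, n)
    E <- if (spec$include_site_random_effect) matrix(NA_real_, n_keep, n)
    kept <- 0L
    acc_tot <- list(beta = numeric(length(state$beta)),
                    alpha = numeric(length(state$alpha)), eps = 0, sd0 = 0)
    for (it in seq_len(config$n_iterations)) {
      adapt <- it <= config$n_burnin
      prev <- state$acc
      state <- mcmc_step(state, adapt = adapt)
      if (!adapt) {
        dacc <- Map(`-`, state$acc, prev)
        acc_tot <- Map(`+`, acc_tot, dacc)
        if ((it - config$n_burnin) %% config$thin == 0L && kept < n_keep) {
          kept <- kept + 1L
          row <- c(state$beta, state$alpha)
          if (spec$include_site_random_effect)
            row <- c(row, state$sd0, state$sd0^2)
          P[kept, ] <- row
          Z[kept, ] <- state$z
          if (spec$include_site_random_effect) E[kept, ] <- state$eps
        }
      }
    }
    params[[ch]] <- P
    z_draws[[ch]] <- Z
    if (spec$include_site_random_effect) eps_draws[[ch]] <- E
    n_post <- config$n_iterations - config$n_burnin
    accept[[ch]] <- lapply(acc_tot, function(a) a / n_post)
  }

  structure(list(params = params, z = z_draws, eps = eps_draws,
                 param_names = pn, spec = spec, config = config,
                 model = "occupancy", site_ids = data$sites$site,
                 accept = accept, prior_only = prior_only),
            class = "occu_draws")
}

#' @export
print.occu_draws <- function(x, ...) {
  cat(sprintf("%s-model posterior draws: %d chains x %d draws, %d parameters\n",
              x$model, length(x$params), nrow(x$params[[1]]),
              length(x$param_names)))
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Pool retained draws across chains
#'
#' @param x an `occu_draws` object.
#' @param ... unused.
#' @return numeric matrix, rows = retained draws of all chains stacked,
#'   columns = parameters.
#' @export
as.matrix.occu_draws <- function(x, ...) {
  do.call(rbind, x$params)
}

#' Exact posterior of the intercept-only model by grid integration
#'
#' Independent verification route for the sampler: with intercept-only
#' occupancy and detection and no random effect, the latent states can be
#' summed out analytically (an all-zero site contributes
#' `psi * prod(1 - p) + (1 - psi)`), leaving a two-parameter marginal
#' likelihood that is integrated numerically over a grid on the logit scale
#' under the intercept priors of [model_spec()].
#'
#' @param data an [occu_data()] object.
#' @param intercept_prior `"uniform"` (default, matching [model_spec()]) or
#'   `"normal"`.
#' @param prior_sd prior sd of the two intercepts on the logit scale when
#'   `intercept_prior = "normal"`.
#' @param grid_n number of grid points per axis (>= 200).
#' @return list with `psi_mean` and `p_mean` (posterior means of the two
#'   probabilities) and `norm` (sum of normalized weights, equal to 1).
#' @export
oracle_posterior_intercept_only <- function(data,
                                            intercept_prior = c("uniform", "normal"),
                                            prior_sd = 10, grid_n = 401) {
  stopifnot(grid_n >= 200)
  intercept_prior <- match.arg(intercept_prior)
  f <- factor(data$visits$site, levels = data$sites$site)
  nv <- as.integer(table(f))
  d <- as.integer(tapply(data$visits$y, f, sum))
  det <- d > 0
  n_det_sites <- sum(det)
  D <- sum(d[det])
  V <- sum(nv[det])
  # counts of all-zero sites by number of visits
  zero_n <- table(nv[!det])

  if (intercept_prior == "uniform") {
    # Logistic(0,1) prior on the logit scale; +-18 leaves < 3e-8 prior mass out
    lg <- seq(-18, 18, length.out = grid_n)
    lw_psi <- stats::dlogis(lg, 0, 1, log = TRUE)
  } else {
    lg <- seq(-4 * prior_sd, 4 * prior_sd, length.out = grid_n)
    lw_psi <- stats::dnorm(lg, 0, prior_sd, log = TRUE)
  }
  psi_g <- inv_logit(lg)
  p_g <- inv_logit(lg)
  lw_p <- lw_psi

  # log marginal likelihood over the (psi, p) grid
  ll <- matrix(0, grid_n, grid_n)
  ll <- ll + n_det_sites * log(psi_g) # rows = psi
  ll <- sweep(ll, 2, D * log(p_g) + (V - D) * log1p(-p_g), `+`)
  for (nm in names(zero_n)) {
    k <- as.integer(nm)
    contrib <- log(outer(psi_g, (1 - p_g)^k) + (1 - psi_g))
    ll <- ll + as.integer(zero_n[[nm]]) * contrib
  }
  lpost <- ll + outer(lw_psi, lw_p, `+`)
  w <- exp(lpost - max(lpost))
  w <- w / sum(w)
  list(psi_mean = sum(rowSums(w) * psi_g),
       p_mean = sum(colSums(w) * p_g),
       norm = sum(w))
}
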