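# The detection-ignoring comparison model: a Bayesian logistic regression of
# the observed (naive) per-site occupancy status on the site covariates and
# the per-site averages of the visit covariates. Deliberately fitted with
# the same priors and the same Metropolis machinery as the occupancy model,
# so any contrast between the two isolates the detection submodel.

#' Build the design of the detection-ignoring logistic regression
#'
#' The response is 1 if the species was detected on any visit to the site,
#' else 0. Site covariates are carried over; visit covariates (humidity,
#' temperature, sampling effort, hour, rainfall) are averaged over each
#' site's visits, and the quadratic temperature term is the square of the
#' averaged (standardized) temperature.
#'
#' @param data an [occu_data()] object with standardized covariates.
#' @return data frame of class `occu_naive_design`: one row per site with
#'   `site`, `response`, the four site covariates, the five averaged visit
#'   covariates and `temperature2`.
#' @export
build_naive_design <- function(data) {
  stopifnot(inherits(data, "occu_data"))
  tmp <- average_temporal_covariates(data)
  out <- data.frame(site = data$sites$site,
                    response = observed_occupancy(data),
                    stringsAsFactors = FALSE)
  for (col in site_covariate_names()) out[[col]] <- data$sites[[col]]
  for (col in visit_covariate_names()) out[[col]] <- tmp[[col]]
  out$temperature2 <- out$temperature^2
  class(out) <- c("occu_naive_design", "data.frame")
  out
}

#' Fit the detection-ignoring logistic regression by MCMC
#'
#' Bayesian logistic regression of naive occupancy on the given terms under
#' Normal(0, `prior_coef_sd`) coefficient priors, sampled by the same
#' adaptive random-walk Metropolis used for the occupancy model's
#' coefficient blocks (same chain, burn-in, thinning and seeding
#' arithmetic).
#'
#' @param design an [build_naive_design()] result.
#' @param terms character vector of design columns to include (besides the
#'   intercept); defaults to all ten covariates.
#' @param config an [chain_config()].
#' @param prior_coef_sd prior sd of slope coefficients on the logit scale.
#' @param intercept_prior intercept prior, as in [model_spec()].
#' @param prior_only replace the likelihood by a constant (draws then target
#'   the prior).
#' @return An `occu_draws` object with `model = "naive"`; parameters are
#'   named `beta0`, `beta_<term>`.
#' @export
fit_naive_sdm <- function(design, terms = NULL, config = chain_config(),
                          prior_coef_sd = 10,
                          intercept_prior = c("uniform", "normal"),
                          prior_only = FALSE) {
  intercept_prior <- match.arg(intercept_prior)
  prior_ld <- coef_prior_ld(list(prior_coef_sd = prior_coef_sd,
                                 intercept_prior = intercept_prior))
  stopifnot(inherits(design, "occu_naive_design"),
            inherits(config, "occu_chain_config"))
  if (is.null(terms))
    terms <- c(site_covariate_names(), "humidity", "temperature",
               "temperature2", "samplingeffort", "hour", "rainfall")
  bad <- setdiff(terms, names(design))
  if (length(bad) > 0)
    stop_occu("unknown naive-model term(s): %s", paste(bad, collapse = ", "),
              class = "occu_unknown_term")
  X <- cbind("(Intercept)" = rep(1, nrow(design)))
  for (t in terms) X <- cbind(X, design[[t]])
  colnames(X) <- c("(Intercept)", terms)
  y <- design$response
  pn <- c("beta0", if (length(terms)) paste0("beta_", terms))
  n_keep <- retained_draws(config, total = FALSE)

  params <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(derive_seed(config$master_seed, 200L + ch))
    beta <- stats::rnorm(ncol(X))
    eta <- drop(X %*% beta)
    scales <- rep(0.5, ncol(X))
    ll_fun <- if (prior_only) function(eta) 0 else function(eta) bern_ll(y, eta)
    if (!is.finite(ll_fun(eta) +
                   sum(vapply(seq_along(beta),
                              function(k) prior_ld(beta[k], k), numeric(1)))))
      stop_occu("non-finite log posterior at initialization",
                class = "occu_init_error")
    P <- matrix(NA_real_, n_keep, ncol(X), dimnames = list(NULL, pn))
    kept <- 0L
    acc_win <- numeric(ncol(X))
    acc_tot <- numeric(ncol(X))
    window <- 0L
    for (it in seq_len(config$n_iterations)) {
      up <- update_coef_block(beta, eta, X, scales, prior_ld, ll_fun)
      beta <- up$coefs
      eta <- up$eta
      if (it <= config$n_burnin) {
        acc_win <- acc_win + up$accepted
        window <- window + 1L
        if (window >= 50L) {
          rate <- acc_win / window
          scales <- ifelse(rate < 0.20, scales * 0.8,
                           ifelse(rate > 0.45, scales * 1.25, scales))
          acc_win <- numeric(ncol(X))
          window <- 0L
        }
      } else {
        acc_tot <- acc_tot + up$accepted
        if ((it - config$n_burnin) %% config$thin == 0L && kept < n_keep) {
          kept <- kept + 1L
          P[kept, ] <- beta
        }
      }
    }
    params[[ch]] <- P
    accept[[ch]] <- list(beta = acc_tot / (config$n_iterations - config$n_burnin))
  }

  structure(list(params = params, z = NULL, eps = NULL,
                 param_names = pn,
                 spec = list(terms = terms, prior_coef_sd = prior_coef_sd,
                             intercept_prior = intercept_prior,
                             include_site_random_effect = FALSE),
                 config = config, model = "naive",
                 site_ids = design$site, accept = accept,
                 prior_only = prior_only),
            class = "occu_draws")
}
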