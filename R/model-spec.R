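#' Model specification for the occupancy analysis
#'
#' Declares which covariates enter the occupancy (ecological) and detection
#' (observational) submodels, whether a site-level random effect is added to
#' the detection linear predictor, and the prior settings. Both linear
#' predictors always include an intercept.
#'
#' Available occupancy terms are the site covariates (`rocks`, `barerock`,
#' `vegetation`, `siteslope`). Detection terms may mix site covariates,
#' visit covariates (`humidity`, `temperature`, `samplingeffort`, `hour`,
#' `rainfall`) and the derived quadratic term `temperature2`, which is the
#' square of the standardized temperature (not re-standardized, so the
#' linear coefficient keeps its interpretation as the slope at the mean
#' temperature). `temperature2` is only allowed together with `temperature`.
#'
#' Priors are deliberately vague: independent Normal(0, `prior_coef_sd`) on
#' every logit-scale slope coefficient and Uniform(0, `prior_re_sd_upper`)
#' on the random-effect standard deviation. The two intercepts default to a
#' Uniform(0, 1) prior on the probability scale (a Logistic(0, 1) density on
#' the logit scale), the standard vague choice for occupancy-model
#' intercepts: a wide normal on a logit-scale intercept is not vague on the
#' probability scale — it concentrates mass at 0 and 1 and visibly biases
#' weakly identified occupancy probabilities toward the boundaries.
#' `intercept_prior = "normal"` switches the intercepts to
#' Normal(0, `prior_coef_sd`) as well.
#'
#' @param occupancy_terms character vector of site covariate names (may be
#'   empty for an intercept-only occupancy submodel).
#' @param detection_terms character vector of covariate names for detection
#'   (may be empty).
#' @param include_site_random_effect add a Normal(0, tau.alpha0) site-level
#'   deviation to the detection linear predictor?
#' @param prior_coef_sd prior standard deviation of regression coefficients
#'   on the logit scale (default 10).
#' @param prior_re_sd_upper upper bound of the uniform prior on the
#'   random-effect sd (default 10).
#' @param intercept_prior `"uniform"` (default) for Uniform(0, 1) on the
#'   inverse-logit of each intercept, or `"normal"` for
#'   Normal(0, `prior_coef_sd`) on the logit scale.
#' @return An object of class `occu_model_spec`.
#' @export
model_spec <- function(occupancy_terms = character(),
                       detection_terms = character(),
                       include_site_random_effect = FALSE,
                       prior_coef_sd = 10,
                       prior_re_sd_upper = 10,
                       intercept_prior = c("uniform", "normal")) {
  intercept_prior <- match.arg(intercept_prior)
  occupancy_terms <- as.character(occupancy_terms)
  detection_terms <- as.character(detection_terms)
  bad <- setdiff(occupancy_terms, site_covariate_names())
  if (length(bad) > 0)
    stop_occu("unknown occupancy term(s): %s", paste(bad, collapse = ", "),
              class = "occu_unknown_term")
  valid_det <- c(site_covariate_names(), visit_covariate_names(),
                 derived_term_names())
  bad <- setdiff(detection_terms, valid_det)
  if (length(bad) > 0)
    stop_occu("unknown detection term(s): %s", paste(bad, collapse = ", "),
              class = "occu_unknown_term")
  if ("temperature2" %in% detection_terms &&
      !"temperature" %in% detection_terms)
    stop_occu("temperature2 requires temperature in the detection terms",
              class = "occu_unknown_term")
  if (anyDuplicated(occupancy_terms) || anyDuplicated(detection_terms))
    stop_occu("duplicated model terms", class = "occu_unknown_term")
  stopifnot(is.numeric(prior_coef_sd), prior_coef_sd > 0,
            is.numeric(prior_re_sd_upper), prior_re_sd_upper > 0)
  structure(list(occupancy_terms = occupancy_terms,
                 detection_terms = detection_terms,
                 include_site_random_effect = isTRUE(include_site_random_effect),
                 prior_coef_sd = prior_coef_sd,
                 prior_re_sd_upper = prior_re_sd_upper,
                 intercept_prior = intercept_prior),
            class = "occu_model_spec")
}

#' The full study model
#'
#' Convenience constructor for the complete specification used in the
#' survey analysis this package is built around: occupancy on all four site
#' covariates; detection on humidity, temperature and its square, the three
#' non-slope site covariates, sampling effort, hour and rainfall, plus a
#' site-level random effect.
#'
#' @param ... passed on to [model_spec()] (prior settings, random-effect
#'   switch).
#' @return An `occu_model_spec`.
#' @export
study_model_spec <- function(...) {
  model_spec(
    occupancy_terms = c("rocks", "barerock", "vegetation", "siteslope"),
    detection_terms = c("humidity", "temperature", "temperature2",
                        "rocks", "barerock", "vegetation",
                        "samplingeffort", "hour", "rainfall"),
    include_site_random_effect = TRUE,
    ...
  )
}

#' @export
print.occu_model_spec <- function(x, ...) {
  cat("occupancy model specification\n")
  cat("  occupancy terms: ",
      if (length(x$occupancy_terms)) paste(x$occupancy_terms, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  cat("  detection terms: ",
      if (length(x$detection_terms)) paste(x$detection_terms, collapse = ", ")
      else "(intercept only)", "\n", sep = "")
  cat("  site random effect in detection:", x$include_site_random_effect, "\n")
  cat(sprintf("  priors: slopes ~ Normal(0, %g); intercepts ~ %s; re sd ~ Uniform(0, %g)\n",
              x$prior_coef_sd,
              if (x$intercept_prior == "uniform") "Uniform(0,1) on probability"
              else sprintf("Normal(0, %g)", x$prior_coef_sd),
              x$prior_re_sd_upper))
  invisible(x)
}

#' MCMC chain configuration
#'
#' @param n_chains number of independent chains (default 3).
#' @param n_iterations iterations per chain, including burn-in.
#' @param n_burnin iterations discarded at the start of each chain; proposal
#'   scales adapt only during this period.
#' @param thin keep every `thin`-th post-burn-in draw. Retained draws per
#'   chain = `floor((n_iterations - n_burnin) / thin)`.
#' @param master_seed integer master seed; every chain derives its own
#'   stream from it, so a run is reproducible bit-for-bit.
#' @return An object of class `occu_chain_config`.
#' @examples
#' # the full-length analysis configuration: 3 x (200000 - 100000)/50 = 6000
#' cc <- chain_config(3, 200000, 100000, 50, master_seed = 1)
#' retained_draws(cc)
#' @export
chain_config <- function(n_chains = 3, n_iterations = 6000, n_burnin = 3000,
                         thin = 3, master_seed = 1) {
  stopifnot(n_chains >= 1, n_iterations >= 1,
            n_burnin >= 0, n_burnin < n_iterations, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 master_seed = as.integer(master_seed)),
            class = "occu_chain_config")
}

#' Retained posterior draws implied by a chain configuration
#'
#' @param config an [chain_config()] object.
#' @param total if `TRUE` (default) the total across chains, else per chain.
#' @return integer number of retained draws.
#' @export
retained_draws <- function(config, total = TRUE) {
  per <- (config$n_iterations - config$n_burnin) %/% config$thin
  if (total) config$n_chains * per else per
}
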