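#' Configuration of the synthetic survey generator
#'
#' Describes a repeated-visit detection/non-detection study to simulate:
#' number of sites, distribution of visit counts, the generating occupancy
#' and detection coefficients (on the logit scale), and the standard
#' deviation of the site-level random effect in detection.
#'
#' The defaults emulate the field design this package targets: 96 sites,
#' each visited 1 to 5 times with all visit counts equally likely (mean 3
#' visits), intercept-only occupancy at probability 0.8 and intercept-only
#' per-visit detection at probability 0.26, with no random effect. Covariate
#' effects are switched on by setting nonzero coefficients.
#'
#' Coefficient order follows the model's linear predictors:
#' \itemize{
#'   \item occupancy (length 5): intercept, `rocks`, `barerock`,
#'     `vegetation`, `siteslope`;
#'   \item detection (length 10): intercept, `humidity`, `temperature`,
#'     `temperature2`, `rocks`, `barerock`, `vegetation`, `samplingeffort`,
#'     `hour`, `rainfall`.
#' }
#'
#' @param n_sites number of surveyed sites.
#' @param visit_probs probabilities of 1..5 visits per site; must sum to 1.
#' @param occupancy_coefs numeric length-5 vector of generating occupancy
#'   coefficients.
#' @param detection_coefs numeric length-10 vector of generating detection
#'   coefficients.
#' @param re_sd standard deviation (>= 0) of the site-level detection
#'   random effect; 0 disables it.
#' @param seed master seed; the covariate, occupancy-state, random-effect
#'   and detection generators each use an independent substream derived from
#'   it, so changing one stage leaves the others unchanged.
#' @param rain_zero_prob probability a visit has exactly zero raw rainfall
#'   (zero-inflation) before standardization; 0 (default) draws rainfall as
#'   standard normal like the other covariates.
#' @param site_cov_corr common pairwise correlation (equicorrelation) among
#'   the raw site covariates, for robustness experiments; 0 (default) draws
#'   them independently.
#' @return An object of class `occu_generator_config`.
#' @export
generator_config <- function(n_sites = 96,
                             visit_probs = rep(0.2, 5),
                             occupancy_coefs = c(stats::qlogis(0.8), 0, 0, 0, 0),
                             detection_coefs = c(stats::qlogis(0.26), rep(0, 9)),
                             re_sd = 0,
                             seed = 1,
                             rain_zero_prob = 0,
                             site_cov_corr = 0) {
  stopifnot(n_sites >= 1, length(visit_probs) == 5, all(visit_probs >= 0),
            abs(sum(visit_probs) - 1) < 1e-8,
            length(occupancy_coefs) == 5, length(detection_coefs) == 10,
            re_sd >= 0, rain_zero_prob >= 0, rain_zero_prob < 1,
            site_cov_corr >= 0, site_cov_corr < 1)
  names(occupancy_coefs) <- c("(Intercept)", site_covariate_names())
  names(detection_coefs) <- c("(Intercept)", "humidity", "temperature",
                              "temperature2", "rocks", "barerock",
                              "vegetation", "samplingeffort", "hour",
                              "rainfall")
  structure(list(n_sites = as.integer(n_sites), visit_probs = visit_probs,
                 occupancy_coefs = occupancy_coefs,
                 detection_coefs = detection_coefs,
                 re_sd = re_sd, seed = as.integer(seed),
                 rain_zero_prob = rain_zero_prob,
                 site_cov_corr = site_cov_corr),
            class = "occu_generator_config")
}

#' Simulate site and visit covariates
#'
#' Draws visit counts from the configured categorical distribution on 1..5,
#' raw covariates as standard normals (site covariates optionally
#' equicorrelated, rainfall optionally zero-inflated), then standardizes
#' every column to mean 0 and sample sd 1 — the scale the model consumes.
#' Deterministic given the configuration seed.
#'
#' @param config an [generator_config()] object.
#' @return list with `sites` (site covariate table) and `visits` (visit
#'   table with `y` initialized to 0, to be filled by
#'   [simulate_detections()]).
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "occu_generator_config"))
  n <- config$n_sites
  set.seed(derive_seed(config$seed, 1L))

  n_visits <- sample(1:5, n, replace = TRUE, prob = config$visit_probs)

  rho <- config$site_cov_corr
  z <- matrix(stats::rnorm(n * 4), n, 4)
  if (rho > 0) {
    u <- stats::rnorm(n)
    z <- sqrt(rho) * u + sqrt(1 - rho) * z
  }
  sites <- data.frame(site = sprintf("s%03d", seq_len(n)))
  for (k in seq_along(site_covariate_names()))
    sites[[site_covariate_names()[k]]] <- standardize(z[, k])

  m <- sum(n_visits)
  site_idx <- rep(seq_len(n), n_visits)
  visits <- data.frame(site = sites$site[site_idx],
                       visit = unlist(lapply(n_visits, seq_len)),
                       y = 0L, stringsAsFactors = FALSE)
  for (col in c("humidity", "temperature", "samplingeffort", "hour"))
    visits[[col]] <- standardize(stats::rnorm(m))
  if (config$rain_zero_prob > 0) {
    wet <- stats::rbinom(m, 1, 1 - config$rain_zero_prob)
    visits$rainfall <- standardize(wet * stats::rexp(m))
  } else {
    visits$rainfall <- standardize(stats::rnorm(m))
  }
  visits <- visits[, c("site", "visit", "y", visit_covariate_names())]
  list(sites = sites, visits = visits)
}

# design matrix of the occupancy linear predictor, canonical column order
occupancy_design <- function(sites) {
  cbind("(Intercept)" = 1, as.matrix(sites[, site_covariate_names()]))
}

# design matrix of the full detection linear predictor used by the
# generator: visit covariates, the derived temperature square, and the
# three site covariates expanded to visit rows
detection_design_full <- function(sites, visits) {
  site_idx <- match(visits$site, sites$site)
  cbind("(Intercept)" = 1,
        humidity = visits$humidity,
        temperature = visits$temperature,
        temperature2 = visits$temperature^2,
        rocks = sites$rocks[site_idx],
        barerock = sites$barerock[site_idx],
        vegetation = sites$vegetation[site_idx],
        samplingeffort = visits$samplingeffort,
        hour = visits$hour,
        rainfall = visits$rainfall)
}

#' Simulate the latent occupancy states
#'
#' Each site's true presence indicator is Bernoulli with success probability
#' inverse-logit of the occupancy linear predictor.
#'
#' @param coefs length-5 occupancy coefficient vector (intercept, `rocks`,
#'   `barerock`, `vegetation`, `siteslope`).
#' @param sites site covariate table as produced by [simulate_covariates()].
#' @param seed RNG seed.
#' @return list with `z` (integer 0/1 vector) and `psi` (the site occupancy
#'   probabilities used).
#' @export
simulate_occupancy_state <- function(coefs, sites, seed = 1) {
  stopifnot(length(coefs) == 5)
  psi <- inv_logit(drop(occupancy_design(sites) %*% coefs))
  set.seed(seed)
  list(z = stats::rbinom(length(psi), 1, psi), psi = psi)
}

#' Simulate detection histories
#'
#' Detections are Bernoulli with success probability `z[site] * p_ij`, where
#' `logit(p_ij)` is the detection linear predictor plus a site-level random
#' deviation `eps_i ~ Normal(0, re_sd^2)`. Unoccupied sites therefore yield
#' structural zeros.
#'
#' @param coefs length-10 detection coefficient vector (see
#'   [generator_config()] for the order).
#' @param re_sd random-effect standard deviation (0 disables it).
#' @param z integer 0/1 vector of true occupancy states, one per site.
#' @param sites,visits covariate tables from [simulate_covariates()].
#' @param seed RNG seed (the random effects and the detections use
#'   substreams derived from it).
#' @return list with `y` (0/1 vector aligned with visit rows), `p` (the
#'   per-visit detection probabilities, random effect included) and `eps`
#'   (the site random effects).
#' @export
simulate_detections <- function(coefs, re_sd, z, sites, visits, seed = 1) {
  stopifnot(length(coefs) == 10, length(z) == nrow(sites))
  site_idx <- match(visits$site, sites$site)
  set.seed(derive_seed(seed, 1L))
  eps <- if (re_sd > 0) stats::rnorm(nrow(sites), 0, re_sd) else numeric(nrow(sites))
  p <- inv_logit(drop(detection_design_full(sites, visits) %*% coefs) +
                   eps[site_idx])
  set.seed(derive_seed(seed, 2L))
  y <- stats::rbinom(length(p), 1, z[site_idx] * p)
  list(y = y, p = p, eps = eps)
}

#' Simulate a complete repeated-visit occupancy study
#'
#' Composes [simulate_covariates()], [simulate_occupancy_state()] and
#' [simulate_detections()] into a ready-to-fit dataset plus a truth record
#' holding everything the generator knew (coefficients, latent states, site
#' occupancy probabilities, per-visit detection probabilities and random
#' effects) for parameter-recovery scoring.
#'
#' @param config an [generator_config()] object.
#' @param out_dir optional directory; when given, `visits.csv`, `sites.csv`
#'   and a flat `truth.json` are written there.
#' @return list with `data` (an [occu_data()] object, covariates already
#'   standardized) and `truth`.
#' @examples
#' sim <- simulate_study(generator_config(n_sites = 50, seed = 42))
#' sim$data
#' sum(sim$truth$z) # true number of occupied sites
#' @export
simulate_study <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "occu_generator_config"))
  cov <- simulate_covariates(config)
  occ <- simulate_occupancy_state(config$occupancy_coefs, cov$sites,
                                  seed = derive_seed(config$seed, 2L))
  det <- simulate_detections(config$detection_coefs, config$re_sd, occ$z,
                             cov$sites, cov$visits,
                             seed = derive_seed(config$seed, 3L))
  cov$visits$y <- det$y
  data <- occu_data(cov$visits, cov$sites, standardized = TRUE)
  truth <- list(z = occ$z, psi = occ$psi, p = det$p, eps = det$eps,
                occupancy_coefs = config$occupancy_coefs,
                detection_coefs = config$detection_coefs,
                re_sd = config$re_sd, seed = config$seed)
  if (!is.null(out_dir)) {
    write_occu_data(data, out_dir)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(data = data, truth = truth)
}
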