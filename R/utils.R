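# Internal numerical and RNG helpers shared across the package.

# Linear predictors are clamped before the inverse-logit so that extreme
# proposals cannot produce p exactly 0 or 1 and -Inf log-likelihoods.
ETA_CLAMP <- 35

clamp_eta <- function(eta) pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)

inv_logit <- function(eta) stats::plogis(clamp_eta(eta))

#' @noRd
stop_occu <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "occuBayes_error")))
}

# Deterministic substream derivation from a master seed.  Each logical
# source of randomness (covariates, latent states, random effects,
# detections, each MCMC chain, each replicate) gets its own substream so
# changing one generator leaves the others untouched.  A multiplicative
# hash keeps the result a valid 32-bit R integer.
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(master_seed) %% m + m) %% m
  as.integer((s * 48271 + as.numeric(index) * 1664525 + 1013904223) %% m)
}

site_covariate_names <- function() c("rocks", "barerock", "vegetation", "siteslope")
visit_covariate_names <- function() {
  c("humidity", "temperature", "samplingeffort", "hour", "rainfall")
}
# temperature2 is a derived model term (square of standardized temperature),
# not a stored column.
derived_term_names <- function() "temperature2"
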