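# Fixture builders used across the test files. Everything is generated in
# code; no data files.

# a tiny hand-specified dataset: site ids, visit counts and detections are
# explicit, covariates filled with fixed (already centered-ish) values
tiny_data <- function(y_by_site, standardized = TRUE, seed = 99) {
  set.seed(seed)
  n <- length(y_by_site)
  ids <- sprintf("t%02d", seq_len(n))
  sites <- data.frame(site = ids,
                      rocks = rnorm(n), barerock = rnorm(n),
                      vegetation = rnorm(n), siteslope = rnorm(n))
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    yi <- y_by_site[[i]]
    data.frame(site = ids[i], visit = seq_along(yi), y = yi,
               humidity = rnorm(length(yi)), temperature = rnorm(length(yi)),
               samplingeffort = rnorm(length(yi)), hour = rnorm(length(yi)),
               rainfall = rnorm(length(yi)))
  }))
  occu_data(visits, sites, standardized = standardized)
}

# a quick simulated dataset at the default study design
quick_sim <- function(seed = 1, ...) {
  simulate_study(generator_config(seed = seed, ...))
}

# independent brute-force evaluator of the complete-data likelihood of one
# site: psi^z (1-psi)^(1-z) * prod Bernoulli(y_j; z * p_j). Used as the
# oracle for both the z full conditional and the model log-likelihood.
site_likelihood_brute <- function(z, psi, p, y) {
  lik <- if (z == 1) psi else (1 - psi)
  for (j in seq_along(y)) {
    pj <- z * p[j]
    lik <- lik * (if (y[j] == 1) pj else 1 - pj)
  }
  lik
}

# fake draws container for summary-level unit tests
fake_draws <- function(chains, param = "x") {
  structure(list(params = lapply(chains, function(v) {
    m <- matrix(v, ncol = 1)
    colnames(m) <- param
    m
  }),
  z = NULL, eps = NULL, param_names = param,
  spec = list(include_site_random_effect = FALSE),
  config = NULL, model = "naive", site_ids = NULL,
  accept = NULL, prior_only = FALSE),
  class = "occu_draws")
}
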