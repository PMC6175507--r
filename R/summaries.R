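# Posterior summaries, convergence diagnostics and the derived quantities
# of the occupancy analysis.

#' Split-chain Gelman-Rubin diagnostic (potential scale reduction factor)
#'
#' Each chain is split in half before comparing between- and within-chain
#' variances, which also exposes within-chain drift; values near 1 indicate
#' convergence and the conventional alarm threshold is 1.1. With zero
#' within-chain variance everywhere (constant chains) the diagnostic is
#' undefined and `NA` is returned rather than an error.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths, at
#'   least 4 draws each) or a draws-by-chains matrix.
#' @return the scale reduction factor, or `NA_real_` when undefined.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  stopifnot(length(chains) >= 2, all(lengths(chains) >= 4),
            length(unique(lengths(chains))) == 1)
  half <- unname(lengths(chains)[1]) %/% 2
  halves <- unlist(lapply(chains, function(x) {
    list(x[seq_len(half)], x[(half + 1):(2 * half)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- half
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(means)
  var_hat <- (n - 1) / n * W + B / n
  sqrt(var_hat / W)
}

#' Cumulative detection probability over repeated surveys
#'
#' Probability of detecting the species at least once in `n` visits to an
#' occupied site, `1 - (1 - p)^n`, where `p` is the per-visit detection
#' probability. Applied per posterior draw of the average detection
#' probability this yields a posterior distribution of survey-design
#' detectability for each candidate number of visits.
#'
#' @param p per-visit detection probability (vectorized).
#' @param n number of visits (positive integer, vectorized).
#' @return `1 - (1 - p)^n`.
#' @examples
#' pstar(0.26, 3) # 1 - 0.74^3
#' @export
pstar <- function(p, n) {
  if (any(p < 0 | p > 1))
    stop_occu("detection probability outside [0, 1]",
              class = "occu_numerical_domain")
  if (any(n < 1 | n != round(n)))
    stop_occu("n must be a positive integer", class = "occu_bad_input")
  1 - (1 - p)^n
}

# per-draw site occupancy probabilities and visit detection probabilities
# reconstructed from the coefficient draws (random effect included)
draw_probabilities <- function(draws, data, chain) {
  spec <- draws$spec
  mats <- build_model_matrices(data, spec)
  P <- draws$params[[chain]]
  kb <- 1L + length(spec$occupancy_terms)
  ka <- 1L + length(spec$detection_terms)
  B <- P[, seq_len(kb), drop = FALSE]
  A <- P[, kb + seq_len(ka), drop = FALSE]
  psi <- inv_logit(B %*% t(mats$X_psi)) # draws x sites
  eta_p <- A %*% t(mats$X_p)
  if (spec$include_site_random_effect && !is.null(draws$eps))
    eta_p <- eta_p + draws$eps[[chain]][, mats$site_idx, drop = FALSE]
  list(psi = psi, p = inv_logit(eta_p))
}

#' Per-draw derived quantities of the occupancy analysis
#'
#' For every retained draw computes the finite-sample number of occupied
#' sites `N.occu` (sum of the latent states over the surveyed sites), the
#' finite-sample occupancy proportion `psi.fs = N.occu / n_sites`, the
#' average occupancy probability over sites `psi.mean`, and the average
#' per-visit detection probability over all realized site-visits `p.mean`
#' (site random effects included, so it describes realized survey
#' detectability).
#'
#' @param draws an `occu_draws` object from [run_occu_mcmc()].
#' @param data the [occu_data()] the model was fitted to.
#' @return data frame with one row per retained draw: `chain`, `N.occu`,
#'   `psi.fs`, `psi.mean`, `p.mean`.
#' @export
derived_quantities <- function(draws, data) {
  stopifnot(inherits(draws, "occu_draws"), draws$model == "occupancy")
  out <- lapply(seq_along(draws$params), function(ch) {
    pr <- draw_probabilities(draws, data, ch)
    nocc <- rowSums(draws$z[[ch]])
    data.frame(chain = ch,
               N.occu = nocc,
               psi.fs = nocc / n_sites(data),
               psi.mean = rowMeans(pr$psi),
               p.mean = rowMeans(pr$p))
  })
  do.call(rbind, out)
}

summary_row <- function(x) {
  q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  c(mean = mean(x), sd = stats::sd(x), q2.5 = q[1], q97.5 = q[2])
}

#' Posterior summary table
#'
#' Pools the retained draws across chains and reports, per parameter, the
#' posterior mean, standard deviation, central 95% credible interval and the
#' split-chain Gelman-Rubin statistic. For an occupancy fit with `data`
#' supplied, rows for the derived quantities (`N.occu`, `psi.fs`,
#' `psi.mean`, `p.mean` and the cumulative detection probabilities
#' `pstar_1` .. `pstar_5`, each computed per draw) are appended.
#'
#' @param draws an `occu_draws` object.
#' @param data optional [occu_data()] used to add the derived-quantity rows
#'   (occupancy fits only).
#' @param pstar_n visit numbers for the cumulative detection rows.
#' @return data frame of class `occu_summary` with columns `parameter`,
#'   `mean`, `sd`, `q2.5`, `q97.5`, `rhat`.
#' @export
summarize_draws <- function(draws, data = NULL, pstar_n = 1:5) {
  stopifnot(inherits(draws, "occu_draws"))
  per_chain <- draws$params
  pooled <- as.matrix(draws)
  if (nrow(pooled) < 2)
    stop_occu("need at least 2 retained draws", class = "occu_bad_input")
  rows <- lapply(draws$param_names, function(pn) {
    cols <- lapply(per_chain, function(P) P[, pn])
    c(summary_row(pooled[, pn]),
      rhat = if (length(per_chain) >= 2 && nrow(per_chain[[1]]) >= 4)
        gelman_rubin(cols) else NA_real_)
  })
  tab <- data.frame(parameter = draws$param_names,
                    do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(data) && draws$model == "occupancy") {
    dq <- derived_quantities(draws, data)
    add <- c("N.occu", "psi.fs", "psi.mean", "p.mean")
    for (nme in add) {
      cols <- split(dq[[nme]], dq$chain)
      tab <- rbind(tab, data.frame(parameter = nme,
                                   t(summary_row(dq[[nme]])),
                                   rhat = if (length(cols) >= 2)
                                     gelman_rubin(cols) else NA_real_))
    }
    for (k in pstar_n) {
      ps <- pstar(dq$p.mean, k)
      cols <- split(ps, dq$chain)
      tab <- rbind(tab, data.frame(parameter = sprintf("pstar_%d", k),
                                   t(summary_row(ps)),
                                   rhat = if (length(cols) >= 2)
                                     gelman_rubin(cols) else NA_real_))
    }
  }
  rownames(tab) <- NULL
  class(tab) <- c("occu_summary", "data.frame")
  tab
}

#' @export
print.occu_summary <- function(x, digits = 3, ...) {
  cat("posterior summary (pooled across chains)\n")
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write retained draws to a delimited file
#'
#' One row per retained draw with its chain and draw index and every model
#' parameter, so external diagnostic tools can consume the output.
#'
#' @param draws an `occu_draws` object.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "occu_draws"))
  tabs <- lapply(seq_along(draws$params), function(ch) {
    data.frame(chain = ch, draw = seq_len(nrow(draws$params[[ch]])),
               draws$params[[ch]], check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
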