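# occuBayes

Bayesian single-season site-occupancy modelling for detection/non-detection
surveys, with a purpose-built MCMC sampler.

Field surveys of secretive species — the motivating case is a survey of a
rock-dwelling amphibian across 96 plots visited one to five times each —
rarely detect a species everywhere it is present. Treating the observed
presence/absence as the truth ("naive" occupancy) confounds where a species
*lives* with where it is *visible*, and biases habitat-effect estimates
toward the conditions under which the species is easy to find. Occupancy
models separate the two processes using the replicate visits.

## The model

For site `i` and visit `j`:

    z_i   ~ Bernoulli(psi_i)          latent true presence
    y_ij  ~ Bernoulli(z_i * p_ij)     observed detection

    logit(psi_i) = beta0 + beta' * x_i              (site covariates)
    logit(p_ij)  = alpha0 + alpha' * w_ij + eps_i   (site + visit covariates)
    eps_i ~ Normal(0, tau.alpha0)                   site random effect

All covariates are standardized (zero mean, unit sample variance); a
quadratic temperature term (the square of the standardized temperature) can
enter the detection submodel. Priors are vague: Uniform(0, 1) on the
inverse-logit of each intercept, Normal(0, 10) on slopes, Uniform(0, 10) on
`sd.alpha0 = sqrt(tau.alpha0)`.

The sampler is a data-augmented Metropolis-within-Gibbs sweep: exact Gibbs
draws of every `z_i` from its closed-form full conditional, adaptive
random-walk Metropolis on the coefficient blocks, vectorized Metropolis on
the site random effects, and a Metropolis update of `sd.alpha0`. Proposal
scales adapt only during burn-in. Everything is reproducible bit for bit
from one master seed.

Derived quantities are computed per posterior draw: the finite-sample number
of occupied sites `N.occu = sum(z_i)`, the occupied proportion
`psi.fs = N.occu / n_sites`, the site-average occupancy `psi.mean`, the
visit-average detection probability `p.mean`, and the cumulative detection
probability `p*(n) = 1 - (1 - p.mean)^n` for `n = 1..5` visits. Convergence
is monitored with a split-chain Gelman–Rubin statistic. A deliberately
"naive" Bayesian logistic regression of the observed occupancy status on the
same covariates (visit covariates averaged per site), fitted with identical
priors and machinery, quantifies what ignoring detection would conclude.

A synthetic-data generator (`simulate_study()`) emulates the survey design —
96 sites, 1–5 visits per site (mean 3), standardized covariates, occupancy
probability 0.8 and per-visit detection probability 0.26 by default — and
returns the full generating truth, so parameter recovery can be scored
without any field data.

## Worked example

```r
library(occuBayes)

sim <- simulate_study(generator_config(seed = 1))   # study-design defaults
sim$data
#> occupancy dataset: 96 sites, 276 visits (1-5 per site)
#>   sites with >=1 detection: 43 (naive occupancy 0.448)
#>   covariates standardized: TRUE

fit <- run_occu_mcmc(sim$data, model_spec(),
                     chain_config(3, 6000, 3000, 3, master_seed = 1))
summarize_draws(fit, data = sim$data)
#> posterior summary (pooled across chains)
#>  parameter   mean    sd   q2.5  q97.5  rhat
#>      beta0  1.893 0.935  0.606  4.184 1.010
#>     alpha0 -1.066 0.197 -1.440 -0.673 1.012
#>     N.occu 81.184 8.427 65.000 95.000 1.016
#>     psi.fs  0.846 0.088  0.677  0.990 1.016
#>   psi.mean  0.839 0.092  0.647  0.985 1.014
#>     p.mean  0.258 0.038  0.192  0.338 1.012
#>    pstar_1  0.258 0.038  0.192  0.338 1.012
#>    pstar_2  0.448 0.055  0.347  0.561 1.012
#>    pstar_3  0.588 0.061  0.472  0.710 1.012
#>    pstar_4  0.692 0.060  0.573  0.808 1.011
#>    pstar_5  0.769 0.056  0.655  0.873 1.011
```

43 of 96 sites had a detection, yet the detection-corrected posterior puts
the number of occupied sites at about 81 (the generating truth for this seed
is 77 occupied sites): per-visit detectability is only ~0.26, so roughly
every second occupied site was missed entirely. The `pstar_n` rows say how
the chance of detecting the species at least once grows with repeat visits
to an occupied site. All split-chain Rhat values are below 1.1. The same
data through the detection-ignoring logistic regression
(`fit_naive_sdm(build_naive_design(sim$data), ...)`) centers its occupancy
intercept near the naive 0.45 — the bias the occupancy model corrects.

Covariate effects are declared through `model_spec()` (e.g.
`model_spec(occupancy_terms = c("rocks", "vegetation"), detection_terms =
c("temperature", "temperature2"), include_site_random_effect = TRUE)`, or
`study_model_spec()` for the full survey model). `run_study_mimic()` and
`run_recovery_suite()` wrap simulate–fit–summarize–score loops;
`inst/cli/occutool.R` exposes the same stages as shell subcommands.

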