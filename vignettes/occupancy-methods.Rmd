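---
title: "Methods: the occuBayes occupancy model, sampler and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the occuBayes occupancy model, sampler and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model implemented by occuBayes, the
sampler that fits it, the choices that were genuinely open when the package
was designed, and what the synthetic-data experiments do and do not
demonstrate.

## The model and its assumptions

occuBayes fits the standard single-season (static) site-occupancy model for
detection/non-detection data from repeat visits. Site `i` has a latent true
presence state and each visit `j` an observed detection:

$$z_i \sim \mathrm{Bernoulli}(\psi_i), \qquad
  y_{ij} \sim \mathrm{Bernoulli}(z_i \, p_{ij})$$

$$\mathrm{logit}(\psi_i) = \beta_0 + \beta^\top x_i, \qquad
  \mathrm{logit}(p_{ij}) = \alpha_0 + \alpha^\top w_{ij} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \tau_{\alpha_0})$$

The assumptions this inherits: the season is closed (no site changes
occupancy between its visits — births, deaths and migration during the
survey window would violate this); detections are independent across visits
given `z_i` and the covariates; false positives do not occur (`y = 1` forces
`z = 1`); and sites are exchangeable given covariates (no residual spatial
autocorrelation). The site random effect `eps` absorbs unmodelled
heterogeneity in *detectability* among sites; it is a detection-side term,
not an occupancy-side one.

Separating `psi` from `p` requires replicate visits. With exactly one visit
everywhere the two intercepts are confounded; the sampler still runs (the
posterior is then prior-dominated along the ridge) and the split-chain
Gelman–Rubin statistic is the intended alarm. This degenerate design is
exercised in the tests as a non-crash + diagnostics contract.

## Data preparation

* Covariates are standardized to mean 0 and **sample** (n−1) standard
  deviation 1. Site covariates are standardized across sites; visit
  covariates across the pooled site×visit records, because that is the scale
  on which the detection submodel operates, and the naive comparison model
  averages those standardized values per site.
* The quadratic temperature term is the square of the **standardized**
  temperature and is *not* re-standardized. This keeps the linear
  coefficient interpretable as the slope at the mean temperature. (Squaring
  first and then standardizing would be an equally coherent convention; one
  had to be picked, and this one preserves the usual polynomial-regression
  reading.)
* Ragged visit histories are represented structurally — a site's likelihood
  runs over its realized visits only; there are no sentinel values.
* A collinearity screen (`check_collinearity()`) reports all covariate pairs
  with |Pearson r| at or above a threshold (0.7 by default, the conventional
  cutoff for this kind of habitat analysis). It is a report, not a gate: the
  model will fit whatever it is given.
* Hour-of-day enters as minutes after midnight before standardization. No
  circular encoding is attempted; for a survey window confined to daylight
  hours a linear + quadratic treatment of time-varying covariates is the
  field's usual compromise.

## Priors

* **Slopes**: Normal(0, sd 10) on the logit scale — effectively flat over
  the plausible range of standardized-covariate effects. `prior_coef_sd` is
  configurable.
* **Intercepts**: Uniform(0, 1) on the probability scale, i.e. a
  Logistic(0, 1) density on the logit scale. This is a deliberate design
  decision: a wide normal on a logit-scale *intercept* is not vague on the
  probability scale — it piles prior mass onto psi ≈ 0 and psi ≈ 1, and in a
  96-site design with per-visit detectability around 0.26 that boundary mass
  visibly drags the weakly identified occupancy probability upward (the
  exact grid-integration oracle shows posterior mean psi moving from ~0.80
  to ~0.92 on the same data when the intercept prior is switched from
  uniform to Normal(0, 10)). Uniform-on-probability intercepts are the
  standard vague choice in the occupancy literature.
  `intercept_prior = "normal"` restores normal intercepts for sensitivity
  analysis.
* **Random-effect sd**: `sd.alpha0` ~ Uniform(0, 10); the model stores the
  sd and reports its square `tau.alpha0` alongside.

## The sampler

One sweep of the Metropolis-within-Gibbs kernel:

1. **Latent states.** Every `z_i` is drawn from its exact full conditional.
   A site with a detection has `P(z_i = 1 | ...) = 1`; an all-zero site has
   `psi_i prod_j (1 - p_{ij})` against `(1 - psi_i)`, computed on the log
   scale (`conditional_z_probability()` is the exported closed form and is
   tested against brute-force enumeration at tolerance 1e-12).
2. **Occupancy coefficients**, one at a time: Gaussian random-walk proposal,
   Metropolis acceptance against the Bernoulli(z | psi) likelihood plus
   prior. Linear predictors are updated incrementally (`eta + x_k * delta`),
   never recomputed from scratch.
3. **Detection coefficients**: same scheme against the detection likelihood,
   which runs over the visits of currently occupied sites only.
4. **Random effects**: all `eps_i` are proposed jointly (they are
   conditionally independent) and accepted/rejected per site; for a
   currently unoccupied site the detection likelihood is flat in `eps_i`, so
   its update reduces to a prior draw via Metropolis.
5. **`sd.alpha0`**: random-walk Metropolis with rejection outside
   (0, upper).

**Adaptation.** Proposal scales start at 0.5 (0.3 for the sd) and are
multiplied by 0.8/1.25 whenever a 50-sweep window's acceptance rate falls
below 20% / above 45%. Adaptation runs only during burn-in; the retained
draws come from a fixed kernel, so the usual invariance argument applies
without diminishing-adaptation caveats.

**Initialization.** `z` starts at the observed detection indicator (the only
assignment with positive posterior support at detection sites), coefficients
at independent Normal(0, 1) draws per chain (over-dispersed starts),
`eps = 0`, `sd.alpha0 = 1`. A non-finite initial log posterior raises an
initialization error instead of running.

**Determinism.** The master seed derives one independent substream per chain
(and the generator derives separate substreams for covariates, occupancy
states, random effects and detections, so changing one stage leaves the
others' draws untouched). Every random decision consumes a fixed number of
uniforms per sweep — acceptance draws are taken unconditionally — so runs are
reproducible bit for bit.

**Numerical safety.** Linear predictors are clamped to ±35 before the
inverse logit, keeping every Bernoulli log-probability finite; all density
arithmetic stays on the log scale.

## Verification strategy

Two independent routes to the same posterior are compared:

* `oracle_posterior_intercept_only()` sums the latent states out
  analytically (an all-zero site contributes `psi prod(1-p) + (1-psi)`) and
  integrates the two-parameter marginal posterior on a 401–801 point logit
  grid. The test suite requires MCMC and oracle posterior means of psi and p
  to agree within 0.02 on a 20-site dataset, and the oracle itself to be
  stable under grid doubling (< 1e-4) and normalized (tol 1e-6).
* With the likelihood replaced by a constant (`prior_only = TRUE`), the
  Metropolis machinery must reproduce its priors: slope draw sd within 5% of
  10, inverse-logit intercept draws matching Uniform(0, 1) moments.

Calibration is checked frequentist-style: 20 replicate simulate-and-fit
experiments at a 500-site, 4-visit design must cover the generating
coefficients with the 95% credible intervals at a rate of at least 85% per
parameter.

## Derived quantities

Computed per retained draw, never from posterior means:

* `N.occu = sum_i z_i` and `psi.fs = N.occu / n_sites` — finite-sample
  quantities about the actual surveyed sites.
* `psi.mean` — the average over sites of `psi_i` in that draw. (The
  alternative reading, the inverse logit of the intercept draw, coincides
  with this for intercept-only models; for covariate models the site
  average is the finite-sample quantity comparable to `psi.fs`, which is why
  it was chosen.)
* `p.mean` — the average of `p_{ij}` over all realized site-visits, with the
  random effect included: it describes realized survey detectability, which
  is what a survey-design question needs.
* `pstar_n = 1 - (1 - p.mean)^n` for `n = 1..5` (the survey's visit range),
  applied to each draw of `p.mean`, yielding a posterior distribution of
  cumulative detectability per visit count. The per-draw pipeline and the
  point formula applied to the posterior-mean p differ (Jensen); the package
  computes the per-draw version and the tests pin that choice. Note the
  plain arithmetic: at `p = 0.26`, `pstar(3) ≈ 0.59` and five visits reach
  ≈ 0.78; claims of near-certain detection after three visits would require
  a per-visit p of about 0.63.

`summarize_draws()` reports posterior mean, sd, central 95% credible
interval and split-chain Rhat per parameter, pooling draws across chains.
The split-chain variant (each chain halved before the between/within
comparison) is used because it also flags within-chain drift; the alarm
threshold is the conventional 1.1. Constant chains make the diagnostic
undefined; it is reported as `NA`, not raised.

## The naive comparison model

`build_naive_design()` collapses the data to one row per site: response = 1
if any visit detected the species; visit covariates averaged over the
site's visits; the quadratic temperature term is the **square of the
averaged** standardized temperature (averaging the squares is the other
defensible convention; squaring the average matches how the term would be
built had the design been single-visit, which is the counterfactual the
naive model represents). `fit_naive_sdm()` is a Bayesian logistic regression
under the identical priors and Metropolis code path, so occupancy-vs-naive
contrasts isolate the detection submodel rather than prior or sampler
differences. The characteristic signature, reproduced in the tests: when a
covariate raises occupancy but lowers detection, the naive model attenuates
(here, underestimates) the occupancy effect.

## The synthetic-data generator

`generator_config()` defaults encode the emulated study design: 96 sites;
visit counts uniform on {1,...,5} (mean 3, matching a design of one to five
visits averaging three); all covariates drawn as independent standard
normals and then standardized; intercept-only occupancy at probability 0.8
and detection at 0.26; no random effect. Options: a zero-inflation
probability for raw rainfall, an equicorrelation knob for site covariates
(for robustness experiments), and arbitrary coefficient vectors in the
canonical term order of the two linear predictors.

What it does **not** emulate: the joint distribution of real habitat
covariates (unpublished and surely not independent normal), spatial
autocorrelation among neighbouring sites, within-season phenology of
detectability, or observer effects beyond the site random effect. Passing
recovery tests therefore demonstrate that the sampler correctly inverts its
own generative model at realistic sizes — the model-correctness question —
not that the model is adequate for any particular field system.

## Problem sizes used by tests and the acceptance script

Chains are run at desk scale: 3 chains × 6,000 iterations, 3,000 burn-in,
thinning 3 (3,000 retained draws) for single fits; 2 × 4,000 for the
20-replicate calibration loop. These lengths were chosen as the point where
the intercept-only posterior means are within Monte-Carlo error ~0.01 of the
grid oracle; the full-length configuration (3 × 200,000, 100,000 burn-in,
thinning 50 → 6,000 retained draws) is one `chain_config()` call away.
Because a single 96-site dataset is itself a high-variance draw (the exact
posterior mean of psi varies with sd ≈ 0.10 across datasets generated at
identical rates), the acceptance script averages posterior means over 8
replicate simulate-and-fit runs (3 for the larger covariate designs) rather
than trusting any single dataset.

## Known limitations

* Single-site Gibbs for `z` plus random-walk Metropolis is robust but not
  the fastest-mixing choice; marginalized or Polya-Gamma samplers would mix
  better for large designs and are deliberately out of scope.
* The random-effect sd under a Uniform(0, 10) prior is weakly identified
  when sites have few visits; expect wide intervals at the study's design.
* `p.mean` and `pstar` describe the surveyed design; they are not
  generalizable detectability constants.
* The naive/occupancy contrast shares one dataset, so it is a paired
  comparison, not an independent replication.
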