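---
title: "Multi-species occupancy models in msoccu: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-species occupancy models in msoccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msoccu)
```

## The model

`msoccu` fits hierarchical Bayesian multi-species occupancy models (MSOM) to
detection/non-detection data gathered on a community of `N` species surveyed
repeatedly (`K` occasions) at `J` sites. Two coupled Bernoulli layers separate
the biological state from the observation process:

* **Occupancy.** The true presence of species `i` at site `j` is a latent
  binary state `z[i,j] ~ Bernoulli(psi[i,j])`, with a logit-linear submodel
  `logit(psi[i,j]) = u_i + sum_c alpha[i,c] * x[j,c]` in standardized
  site-level covariates (in the motivating application: elevation, forest
  cover and anthropogenic habitat cover within a buffer around each site).
* **Detection.** The record on one occasion is
  `x[i,j,k] ~ Bernoulli(p[i,j,k] * z[i,j])`: a species can only be detected
  where it is present, and even then only with probability
  `logit(p[i,j,k]) = v_i + sum_c beta[i,c] * w[j,k,c]`. Detection covariates
  may vary by occasion (date, time, humidity, temperature) or be site-level
  attributes that affect detectability (understory height, wood stem
  density); the latter are broadcast over occasions. Which covariates enter
  each submodel is configuration (`ModelSpec`), not code: the appropriate
  detection set differs between taxa and survey methods.

The community layer is what makes the model *multi-species*: every
species-level effect family (the intercepts `u`, `v` and each coefficient
column of `alpha`, `beta`) is drawn from a normal hyper-distribution,
`u_i ~ N(mu_u, sigma_u)` and so on. This partial pooling is the point of the
approach — species with one or two detections borrow strength from the
community and still get usable (if wide) posteriors, which matters because
vertebrate survey data are dominated by rare species.

Unsurveyed (site, occasion) cells are recorded in an explicit survey mask and
excluded from every likelihood and count. Mixed survey designs (camera
nights, transects, quadrats, pooled seasons) produce ragged occasion
structures, so the long input format carries an occasion manifest per site
rather than assuming a rectangular design.

## Priors

The source analyses cite prior-choice recommendations for occupancy models
without printing the distributions, so the package fixes its own weakly
informative defaults, configurable in `ModelSpec`:

* community hyper-means: `Normal(0, sd = 2.25)` on the logit scale. After the
  inverse logit this is close to uniform on the probability scale, avoiding
  the prior mass spikes at 0 and 1 that a wide logit-normal (say sd 10)
  would induce;
* community hyper-sds: `Uniform(0, 5)`. An sd of 5 on the logit scale already
  allows essentially species-specific probabilities anywhere in (0.01, 0.99),
  so the bound is not restrictive in practice.

Individual effect families can instead be *fixed* (`fixedHyperMean`,
`fixedHyperSd`), which turns off their hyper-updates; the single-species toy
model used to validate the sampler against quadrature uses this.

## The sampler

`runMcmc()` implements Metropolis-within-Gibbs with data augmentation,
chosen because each conditional is either closed-form or low-dimensional:

1. **Latent occupancy** `z[i,j]` has an exact Bernoulli full conditional:
   probability 1 where the species was detected, and
   `psi * prod_k(1-p) / (psi * prod_k(1-p) + 1 - psi)` over surveyed
   occasions otherwise. Sampling z exactly (rather than marginalizing inside
   a joint proposal) keeps every other update conditionally independent
   across species.
2. **Species effects** update by scalar random-walk Metropolis, one effect
   family at a time across all species (given z and the hyper-parameters the
   N proposals are independent).
3. **Hyper-means** are conjugate normal Gibbs draws.
4. **Hyper-sds** update by random-walk Metropolis on the log scale (with the
   Jacobian), respecting the uniform prior support.

Proposal scales adapt by Robbins–Monro (`scale <- scale *
exp(gamma_t * (accept - 0.44))`, `gamma_t = min(0.25, 1/sqrt(t))`) toward the
0.44 acceptance rate that is optimal for scalar random walks, and adaptation
is frozen at the end of burn-in so the retained draws come from a fixed,
detailed-balance-preserving kernel. Post-burn-in acceptance rates are stored
per family (`acceptanceRates()`); on the package's synthetic scenarios they
land near 0.44, and the test suite asserts the [0.15, 0.6] window.

The chain loop is implemented twice: in C++ (the default) and in plain R.
Both follow the same update order and the same R-RNG call sequence, so a
given seed produces *identical* draws from either engine — the R version is
the readable reference and a regression check on the compiled one, and the
test suite asserts bit-equality. Per-chain seeds derive deterministically
from the base seed plus the chain index; a fit is therefore reproducible
bit-for-bit from its configuration.

The default run protocol (3 chains × 150,000 iterations, burn-in 50,000,
thinning 100 → 3,000 retained draws) matches the long-run settings used for
full field datasets. The test suite and acceptance script use shortened
chains (3 × 15,000, burn-in 5,000, thinning 10 for the 25-species recovery
study; smaller still for unit fixtures) — sizes chosen so the whole suite
runs on a laptop while leaving the checks well-powered.

## Convergence and goodness of fit

`gelmanRubin()` computes the split-chain, rank-normalized potential scale
reduction factor: each chain is halved, pooled draws are transformed to
normal scores of average ranks, and the classic R-hat formula is applied to
the split chains. This variant is strictly more conservative than the
original statistic and robust to heavy tails. The usual 1.1 threshold
triggers a prominent warning (never a hard failure) in the pipeline, since
diagnostics are meant to be inspected, not to abort an analysis.

`bayesianPValue()` measures fit by a posterior-predictive check. The
discrepancy is a stabilized Pearson chi-square on species-by-site detection
totals: per retained draw, `E[i,j] = psi[i,j] * sum_k p[i,j,k]` over surveyed
occasions (marginal over z) and `chi2 = sum (O - E)^2 / (E + 0.5)`. A
replicate dataset is simulated from the model at the same draw and scored
identically; the Bayesian p-value is `Pr(chi2_obs > chi2_sim)`, with values
outside (0.05, 0.95) indicating lack of fit. The marginal (psi-based)
expectation is the default because it scores the model as a whole;
`conditionOnZ = TRUE` switches to the sampled latent state for users who want
a detection-submodel-only check. The `+ 0.5` stabilizer bounds the statistic
when expected counts are near zero; the source analyses specify only "a
chi-square discrepancy", so the precise form is a documented package choice.

## Effect classes and summaries

Posterior summaries are pooled-chain means with equal-tailed 95% credible
intervals from linear-interpolation percentiles (R's quantile type 7) —
the convention of JAGS-era summary tables; highest-posterior-density
intervals are deliberately not offered to keep summaries stable under
reparameterization of tails.

Covariate effects are graded per species as:

* **strong** — the 95% CI excludes zero (this rule is exact and matches how
  "significant" effects are flagged in community occupancy tables);
* **moderate** — the CI contains zero but at least 80% of posterior mass lies
  on one side ("contained but not centered on zero");
* **weak** — anything else (roughly centered on zero).

"Centered on zero" has no canonical operationalization; the 0.80 side-mass
threshold is the package's documented, configurable choice. Only the strong
class is therefore comparable across implementations.

## Detection-corrected richness

Two complementary richness estimators are provided:

* `estimatedRichness()` sums the stored latent-occupancy draws:
  `R_j = sum_i z[i,j]` per draw, then posterior mean and CI. Because z is
  forced to 1 wherever a detection occurred, estimated richness is bounded
  below by observed richness at every site and every draw — the
  detection-correction can only add species, never remove them. Group-level
  richness counts species with z = 1 anywhere in the group.
* `predictRichness()` computes the smooth expected-richness surface
  `sum_i psi_i(x)` over a covariate grid, averaged over draws. The
  expectation over psi (rather than thresholded z draws) is unbiased for
  posterior-expected richness and produces the continuous surfaces used for
  mapping predictions; it requires the grid to be standardized with the
  *fit's* scaling (`applyScaling(grid, scalingInfo(fit)$site)`), never
  re-standardized on its own sample.

Richness is reported over the observed species pool only: the package does
not augment the community with never-detected hypothetical species
(no superpopulation/N-augmentation), matching analyses that report richness
of detected species.

## Covariate preparation

`standardizeCovariates()` centers and scales with the sample sd (n−1
denominator — not stated in most method sections; this is the common
convention) and records the scaling so raw values are always recoverable and
grids can be placed on a fit's scale. `screenCollinearity()` applies the
usual thresholds (pairwise Pearson |r| > 0.60, VIF > 3) by iteratively
dropping the worst offender — most |r|-violating partners first, ties broken
by higher VIF, then alphabetically. The thresholds are standard; the
*order* of dropping is rarely stated anywhere, so the deterministic
worst-first rule is the package's choice and is what makes screening
reproducible. `poolHabitatCovers()` aggregates seven land-use/land-cover
fractions into three ecologically homogeneous classes (forest, degraded
forest, anthropogenic), conserving total cover per site.

## The synthetic-community generator

`simulateCommunity()` draws species effects from the community
hyper-distributions, then the two Bernoulli layers, exactly the structure
the sampler assumes — so parameter-recovery tests are well-posed.
`presetScenario()` registers named truth settings: `"null"` (all hyper-means
zero) and four taxon scenarios whose occupancy/detection hyper-means are set
to published community-level estimates for terrestrial-vertebrate
communities along a forest-to-urban gradient (the mammal scenario:
elevation −0.404, forest +2.404, anthropogenic −1.812 on the logit scale).
Two generator settings are package choices, stated prominently because
recovery difficulty depends on them:

* community hyper-sds default to **1.0** (they are not part of the published
  community summaries); larger values make species more idiosyncratic and
  coverage harder;
* intercept hyper-means default to **0** (baseline occupancy and detection
  0.5 at average covariates), also not published.

Occasion missingness is simulated as independent Bernoulli dropout per
(site, occasion) at a configurable rate (default 0), with at least one
surveyed occasion preserved per site.

What the generator deliberately does **not** emulate: spatially
autocorrelated covariate fields, structured missingness tied to habitat
(e.g. no cameras in settlements), phylogenetic correlation among species
effects, and unmodeled detection heterogeneity (observer effects,
behavioral responses). Passing recovery tests on this generator therefore
demonstrates the estimator is correct *under its own assumptions*; it does
not certify robustness to the violations real field data carry.

## Numerical choices

* Linear predictors are clipped to ±35 before the inverse logit, keeping all
  probabilities strictly inside (0, 1) in double precision; the clip changes
  results by less than 1e−15 and removes overflow paths entirely.
* Likelihoods accumulate in log space; `log(1 + exp(x))` is evaluated
  stably.
* The marginal likelihood of a species-site history sums the latent state
  analytically (`psi * prod p^x (1-p)^(1-x)` with a detection;
  `psi * prod(1-p) + (1-psi)` without; 1 for a fully unsurveyed history) and
  is tested to 1e−12 against explicit enumeration over z.
* Constant covariates are rejected at standardization (named in the error);
  fits with zero detections are rejected because the detection submodel is
  then unidentified.
* Posterior persistence writes 17 significant digits, which round-trips
  doubles exactly; the loader restores a fit bit-for-bit.

## Known limitations

* Single-season (static) occupancy only: no colonization/extinction
  dynamics, and no spatial autocorrelation in occupancy.
* The chi-square GOF statistic aggregates over occasions and scores each
  species-site cell independently; misfit that only reorders detections
  within a site-occasion profile, or that lives in cross-species
  co-occurrence, is invisible to it. More generally, detection patterns the
  model can represent exactly — e.g. deterministic all-or-nothing sites,
  which the latent state absorbs with a detection probability near 1 —
  produce no discrepancy at all; the statistic has power against
  overdispersion of detection totals, not against every conceivable
  misfit.
* With very small communities (a handful of species) the hyper-sds are
  weakly identified and mix slowly; the R-hat warning will flag this, and
  longer chains or fixed hyper-sds are the remedies.
* The effect-class boundary between moderate and weak depends on the 0.80
  side-mass convention; comparisons across packages should rely on the
  strong class only.
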