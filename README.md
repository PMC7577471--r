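# msoccu — Bayesian multi-species occupancy models

`msoccu` estimates how land use, habitat and survey conditions shape the
occurrence of whole communities of species — mammals, birds, reptiles,
amphibians — from repeated detection/non-detection surveys, while correcting
for the fact that a species present at a site is not always detected. It is
aimed at community ecologists and conservation analysts working with
camera-trap, transect, point-count or quadrat data.

## The model

Occurrence and observation are separated into two Bernoulli layers. The true
presence of species *i* at site *j* is latent:

    z[i,j] ~ Bernoulli(psi[i,j])
    logit(psi[i,j]) = u_i + alpha1_i * elevation_j
                          + alpha2_i * forest_j
                          + alpha3_i * anthropogenic_j

and the record on survey occasion *k* is conditioned on presence:

    x[i,j,k] ~ Bernoulli(p[i,j,k] * z[i,j])
    logit(p[i,j,k]) = v_i + beta_i' * w[j,k]

with detection covariates *w* such as date, time, humidity, temperature,
understory height and wood stem density (the set is configurable per
dataset). Species-level effects are drawn from community hyper-distributions
(`u_i ~ N(mu_u, sigma_u)` etc.), so rare species borrow strength from the
community. Inference is by a custom Metropolis-within-Gibbs sampler with
exact data augmentation of `z` (compiled chain loop, bit-reproducible from a
seed), with split-chain rank-normalized Gelman–Rubin diagnostics, a
posterior-predictive chi-square Bayesian p-value, effect-strength
classification from credible intervals, and detection-corrected species
richness per site or over a covariate grid.

The methods vignette (`vignettes/msom-methods.Rmd`) documents the priors,
the sampler, and every numerical and design choice in detail.

## Worked example

Simulate a 25-species community at 35 sites with 6 occasions from the
mammal-community preset (occupancy hyper-means: elevation −0.404, forest
+2.404, anthropogenic −1.812), fit it with shortened chains, and summarize:

```r
library(msoccu)

preset <- presetScenario("mmr_mammals")
sim <- simulateCommunity(preset, N = 25, J = 35, K = 6, seed = 11)
spec <- ModelSpec(preset$occupancyCovariates, preset$detectionCovariates)
cfg <- McmcConfig(chains = 3, iterations = 15000, burnin = 5000,
                  thin = 10, baseSeed = 42)
fit <- runMcmc(sim$data, sim$covariates$site, sim$covariates$occasion,
               spec, cfg)

maxRhat(fit)
summarizePosterior(fit, c("mu.alpha.elevation", "mu.alpha.forest",
                          "mu.alpha.anthropogenic"))
head(estimatedRichness(fit, sim$data), 3)
```

```
> maxRhat(fit)
[1] 1.003043
> summarizePosterior(fit, ...)
               parameter       mean      ciLow     ciHigh degenerate
1     mu.alpha.elevation -0.1701406 -0.7873932  0.4102711      FALSE
2        mu.alpha.forest  2.1852454  1.6673015  2.7797562      FALSE
3 mu.alpha.anthropogenic -2.0661469 -2.7294409 -1.4812078      FALSE
> head(estimatedRichness(fit, sim$data), 3)
   group observed     mean ciLow ciHigh
1 site01        9 9.839667     9     11
2 site02        2 2.031333     2      3
3 site03        8 8.779000     8     10
```

All three community hyper-means are recovered: each 95% credible interval
covers the value the community was simulated at, the forest effect is
strongly positive and the anthropogenic effect strongly negative — the
qualitative signature expected for a forest-associated mammal community
along an urbanization gradient. `estimatedRichness()` returns, per site, the
observed species count alongside the posterior mean and interval of the
detection-corrected count; the corrected mean is never below the observed
count, because a detected species is certainly present.

`runPipeline("config.yaml")` chains the whole analysis (reading long-format
CSV records with an occasion manifest, covariate standardization and
collinearity screening, fitting, diagnostics, goodness-of-fit, summary
tables and a reproducible run manifest); `inst/scripts/msoccu.R` is a thin
command-line wrapper with `simulate`, `run`, `summarize`, `richness` and
`predict` subcommands.

## Using field data

Detection records are long-format CSV (`species,site,occasion,detected`)
with a `site,occasion` manifest marking surveyed occasions — absent record
rows on surveyed occasions mean non-detection; occasions absent from the
manifest are treated as not surveyed. Covariates are CSV keyed by `site` or
`site,occasion`. Spreadsheet-based datasets should be exported sheet-by-sheet
to this layout (one directory per taxon with `detections.csv`,
`manifest.csv`, `site_covariates.csv`, optionally
`occasion_covariates.csv`) and loaded with `importSupplementaryData()`.

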