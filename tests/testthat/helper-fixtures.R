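# Shared fixtures: small simulated communities and quick fits.

# Small community from a preset, deterministic in `seed`.
smallSim <- function(preset = "null", N = 6, J = 12, K = 4, seed = 1,
                     missingRate = 0) {
  simulateCommunity(presetScenario(preset), N = N, J = J, K = K, seed = seed,
                    missingRate = missingRate)
}

# Short fit of a simulated community; fast but long enough to mix on the
# small fixtures.
quickFit <- function(sim, preset = "null", chains = 2, iterations = 1200,
                     burnin = 400, thin = 4, seed = 99, storeZ = TRUE) {
  ps <- presetScenario(preset)
  spec <- ModelSpec(occupancyCovariates = ps$occupancyCovariates,
                    detectionCovariates = ps$detectionCovariates)
  cfg <- McmcConfig(chains = chains, iterations = iterations, burnin = burnin,
                    thin = thin, baseSeed = seed, storeZ = storeZ)
  runMcmc(sim$data, sim$covariates$site, sim$covariates$occasion, spec, cfg)
}

# Hand-rolled marginal likelihood by explicit enumeration over z in {0, 1}:
# the independent oracle for the analytic marginal.
enumMarginalLik <- function(history, psi, p, mask = NULL) {
  K <- length(history)
  if (is.null(mask)) mask <- rep(1, K)
  obs <- mask == 1
  lik <- 0
  for (zv in c(0, 1)) {
    pz <- if (zv == 1) psi else 1 - psi
    cond <- 1
    for (k in which(obs)) {
      pk <- p[k] * zv
      cond <- cond * (if (history[k] == 1) pk else 1 - pk)
    }
    lik <- lik + pz * cond
  }
  lik
}

# Build a PosteriorSamples object directly from a list of per-chain draw
# matrices (used to test summarizers on exactly known draws).
fakeSamples <- function(chainDraws, species = "sp01", sites = "site01",
                        spec = ModelSpec()) {
  per <- nrow(chainDraws[[1L]])
  cfg <- McmcConfig(chains = length(chainDraws), iterations = per, burnin = 0,
                    thin = 1, baseSeed = 1, storeZ = FALSE)
  new("PosteriorSamples",
      draws = chainDraws, zDraws = list(), config = cfg, modelSpec = spec,
      species = species, sites = sites, scaling = list(),
      acceptance = numeric())
}
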