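# MCMC sampler behaviour, diagnostics and goodness-of-fit plumbing.

test_that("retained draw count follows the (iterations - burnin) / thin rule", {
  cfg <- McmcConfig(chains = 3, iterations = 150000, burnin = 50000, thin = 100)
  expect_equal(retainedPerChain(cfg), 1000L)
  expect_equal(cfg@chains * retainedPerChain(cfg), 3000L)
  expect_error(McmcConfig(iterations = 100, burnin = 100), "burnin")
})

test_that("identical seeds reproduce fits bit-exactly; seeds matter", {
  sim <- smallSim(N = 4, J = 8, K = 3, seed = 2)
  f1 <- quickFit(sim, iterations = 600, burnin = 200, seed = 7)
  f2 <- quickFit(sim, iterations = 600, burnin = 200, seed = 7)
  expect_identical(posteriorDraws(f1), posteriorDraws(f2))
  expect_identical(latentOccupancyDraws(f1), latentOccupancyDraws(f2))
  f3 <- quickFit(sim, iterations = 600, burnin = 200, seed = 8)
  expect_false(identical(posteriorDraws(f1), posteriorDraws(f3)))
})

test_that("compiled and reference engines draw identical chains", {
  sim <- smallSim(N = 3, J = 6, K = 3, seed = 5)
  ps <- presetScenario("null")
  spec <- ModelSpec(ps$occupancyCovariates, ps$detectionCovariates)
  cfg <- McmcConfig(chains = 2, iterations = 300, burnin = 100, thin = 2,
                    baseSeed = 13)
  fc <- runMcmc(sim$data, sim$covariates$site, sim$covariates$occasion,
                spec, cfg, engine = "cpp")
  fr <- runMcmc(sim$data, sim$covariates$site, sim$covariates$occasion,
                spec, cfg, engine = "R")
  expect_identical(posteriorDraws(fc), posteriorDraws(fr))
  expect_identical(latentOccupancyDraws(fc), latentOccupancyDraws(fr))
  expect_equal(acceptanceRates(fc), acceptanceRates(fr))
})

test_that("every retained z draw respects detections and adaptation targets hold", {
  sim <- smallSim(N = 5, J = 10, K = 4, seed = 12, missingRate = 0.15)
  fit <- quickFit(sim, iterations = 2000, burnin = 800, seed = 3)
  det <- apply(detectionArray(sim$data), c(1, 2), sum) > 0
  for (z in latentOccupancyDraws(fit)) {
    expect_true(all(z[array(det, dim(z))] == 1))
    expect_true(all(z %in% c(0, 1)))
  }
  acc <- acceptanceRates(fit)
  expect_true(all(acc[!is.na(acc)] >= 0.15 & acc[!is.na(acc)] <= 0.6))
})

test_that("degenerate inputs are rejected with clear messages", {
  x <- array(0, c(2, 4, 2))
  dd <- detectionData(x)
  ps <- presetScenario("null")
  expect_error(runMcmc(dd, spec = ModelSpec()), "no detections")

  sim <- smallSim(N = 3, J = 6, K = 3, seed = 5)
  raw <- unstandardizeCovariates(sim$covariates$site)
  spec <- ModelSpec(ps$occupancyCovariates, ps$detectionCovariates)
  expect_error(runMcmc(sim$data, raw, sim$covariates$occasion, spec,
                       McmcConfig(1, 200, 100, 1)), "standardized")
})

test_that("R-hat separates mixed from unmixed chains", {
  # chains that are exact copies of each other
  set.seed(41)
  m <- matrix(rnorm(500), 500, 1, dimnames = list(NULL, "theta"))
  expect_lte(gelmanRubin(list(m, m))["theta"], 1.01)

  # two chains centered 10 sds apart must be flagged
  set.seed(42)
  a <- matrix(rnorm(500, 0, 1), 500, 1, dimnames = list(NULL, "theta"))
  b <- matrix(rnorm(500, 10, 1), 500, 1, dimnames = list(NULL, "theta"))
  expect_gt(gelmanRubin(list(a, b))["theta"], 1.5)

  expect_error(gelmanRubin(list(a)), "2 chains")

  # well-mixed chains from a real fit converge (enough species that the
  # community hyper-sds are informed and mix)
  sim <- smallSim(N = 12, J = 15, K = 4, seed = 6)
  fit <- quickFit(sim, chains = 3, iterations = 8000, burnin = 3000, thin = 5,
                  seed = 21)
  expect_lt(maxRhat(fit), 1.1)
})

test_that("chi-square discrepancies are deterministic per draw", {
  sim <- smallSim(N = 4, J = 8, K = 3, seed = 8)
  fit <- quickFit(sim, iterations = 800, burnin = 400, seed = 5)
  g1 <- bayesianPValue(fit, sim$data, sim$covariates$site,
                       sim$covariates$occasion, seed = 2)
  g2 <- bayesianPValue(fit, sim$data, sim$covariates$site,
                       sim$covariates$occasion, seed = 2)
  expect_identical(g1@chi2Obs, g2@chi2Obs)
  expect_identical(bayesP(g1), bayesP(g2))
  expect_true(bayesP(g1) >= 0 && bayesP(g1) <= 1)
  expect_equal(bayesP(g1), mean(g1@chi2Obs > g1@chi2Sim))
})

test_that("posterior fits persist to text and reload bit-exactly", {
  tmp <- withr::local_tempdir()
  sim <- smallSim(N = 3, J = 6, K = 3, seed = 14)
  fit <- quickFit(sim, iterations = 400, burnin = 200, seed = 31)
  dir <- file.path(tmp, "fit")
  writePosteriorSamples(fit, dir)
  back <- readPosteriorSamples(dir)
  expect_identical(posteriorDraws(back), posteriorDraws(fit))
  expect_equal(latentOccupancyDraws(back), latentOccupancyDraws(fit))
  expect_equal(scalingInfo(back), scalingInfo(fit))
  expect_equal(retainedPerChain(mcmcConfig(back)), retainedPerChain(mcmcConfig(fit)))
})
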