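# Posterior summarization, effect classes, richness estimation/prediction.

test_that("summarize uses pooled means and interpolated percentiles", {
  # draws 1..1000 split over two chains
  d1 <- matrix(1:500, 500, 1, dimnames = list(NULL, "theta"))
  d2 <- matrix(501:1000, 500, 1, dimnames = list(NULL, "theta"))
  s <- fakeSamples(list(d1, d2))
  row <- summarizePosterior(s, "theta")
  expect_equal(row$mean, 500.5)
  expect_equal(row$ciLow, 25.975)      # 2.5th percentile, linear interpolation
  expect_equal(row$ciHigh, 975.025)
  expect_false(row$degenerate)

  const <- fakeSamples(list(matrix(2, 200, 1, dimnames = list(NULL, "c"))))
  rowC <- summarizePosterior(const, "c")
  expect_equal(rowC$mean, 2)
  expect_true(rowC$degenerate)

  expect_error(summarizePosterior(s, "nope"), "unknown parameter")
})

test_that("credible bounds bracket at least 95% of draws", {
  set.seed(77)
  m <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
  s <- fakeSamples(list(m))
  rows <- summarizePosterior(s)
  for (k in 1:2) {
    inside <- mean(m[, k] >= rows$ciLow[k] & m[, k] <= rows$ciHigh[k])
    expect_gte(inside, 0.95 - 1 / 1000)
  }
})

test_that("effect classes follow the credible-interval rules", {
  set.seed(61)
  strong <- rnorm(1000, 2.4, 0.6)     # interval well away from zero
  clS <- classifyEffect(strong)
  expect_equal(clS$label, "strong")
  expect_equal(clS$sign, "positive")

  allPos <- runif(500, 0.1, 1)
  expect_equal(classifyEffect(allPos)$label, "strong")
  expect_equal(classifyEffect(allPos)$sideMass, 1)

  weak <- rnorm(1000, 0, 1)
  expect_equal(classifyEffect(weak)$label, "weak")

  moderate <- rnorm(1000, 0.9, 1)     # zero inside but most mass positive
  clM <- classifyEffect(moderate)
  expect_equal(clM$label, "moderate")
  expect_equal(clM$sign, "positive")

  # strong classification is invariant to monotone rescaling
  expect_equal(classifyEffect(strong * 3.7)$label, "strong")
  expect_equal(classifyEffect(strong / 100)$label, "strong")
})

test_that("effect tallies count classes and negative fractions", {
  classes <- data.frame(
    label = c(rep("strong", 13), rep("moderate", 11), "weak"),
    sign = c(rep("negative", 13), rep("negative", 11), "positive")
  )
  tal <- effectTally(classes)
  expect_equal(tal$n, 25)
  expect_equal(tal$counts["strong", "negative"], 13L)
  expect_equal(tal$pctStrong, 52)     # 13 of 25 species
  expect_equal(tal$pctNegative, 96)

  empty <- effectTally(classes[0, ])
  expect_equal(sum(empty$counts), 0)
  expect_equal(empty$pctNegative, 0)
})

test_that("estimated richness brackets observed richness from below", {
  sim <- smallSim(N = 6, J = 10, K = 4, seed = 23)
  fit <- quickFit(sim, iterations = 1000, burnin = 400, seed = 9)
  rich <- estimatedRichness(fit, sim$data)
  expect_equal(rich$group, siteIds(sim$data))
  expect_true(all(rich$mean >= rich$observed))
  expect_true(all(rich$ciLow >= rich$observed))

  # per-draw richness equals a brute-force count of the z matrix
  z <- latentOccupancyDraws(fit)[[1]]
  for (r in c(1, dim(z)[3])) {
    expect_equal(colSums(z[, , r]),
                 vapply(seq_len(ncol(z)), function(j) sum(z[, j, r]), numeric(1)))
  }

  # grouping: species with z = 1 anywhere in the group
  grouping <- setNames(rep(c("g1", "g2"), each = 5), siteIds(sim$data))
  rg <- estimatedRichness(fit, sim$data, grouping)
  expect_equal(rg$group, c("g1", "g2"))
  expect_true(all(rg$mean >= rg$observed))
  expect_true(all(rg$mean <= length(speciesIds(sim$data))))

  noZ <- quickFit(sim, iterations = 600, burnin = 200, seed = 9, storeZ = FALSE)
  expect_error(estimatedRichness(noZ, sim$data), "storeZ")
})

test_that("sites where every species was seen have estimated = observed", {
  N <- 3; J <- 4; K <- 3
  x <- array(rbinom(N * J * K, 1, 0.4), c(N, J, K))
  x[, 1, 1] <- 1                      # all species detected at site 1
  dd <- detectionData(x)
  covs <- genCovariates(J, K, siteCovariates = c("elevation", "forest", "anthropogenic"),
                        occasionCovariates = c("date", "time"), seed = 2)
  ps <- presetScenario("null")
  spec <- ModelSpec(ps$occupancyCovariates, ps$detectionCovariates)
  fit <- runMcmc(dd, covs$site, covs$occasion, spec,
                 McmcConfig(2, 600, 200, 2, baseSeed = 4))
  rich <- estimatedRichness(fit, dd)
  expect_equal(rich$mean[1], 3)
  expect_equal(rich$ciLow[1], 3)
  expect_equal(rich$ciHigh[1], 3)
})

test_that("richness prediction sums occupancy probabilities over species", {
  # point-mass posterior: u = 0 for 10 species, intercept-only model
  N <- 10
  cn <- c(paste0("u[", 1:N, "]"), paste0("v[", 1:N, "]"),
          "mu.u", "mu.v", "sigma.u", "sigma.v")
  m <- matrix(0, 200, length(cn), dimnames = list(NULL, cn))
  s <- fakeSamples(list(m), species = sprintf("sp%02d", 1:N), sites = "site01")
  grid <- covariateTable(matrix(0, 3, 0), sites = paste0("g", 1:3))
  pr <- predictRichness(s, grid)
  expect_equal(pr$richness, rep(5, 3))       # 10 species at psi 0.5

  # all-zero covariates reduce to the sum of inverse-logit intercepts
  set.seed(91)
  us <- matrix(rnorm(200 * N), 200, N)
  m2 <- m; m2[, 1:N] <- us
  s2 <- fakeSamples(list(m2), species = sprintf("sp%02d", 1:N), sites = "site01")
  pr2 <- predictRichness(s2, grid, ci = FALSE)
  expect_equal(pr2$richness, rep(mean(rowSums(plogis(us))), 3), tolerance = 1e-12)
  expect_true(all(pr2$richness >= 0 & pr2$richness <= N))
})

test_that("negative anthropogenic effects make predicted richness decline", {
  sim <- smallSim("mmr_mammals", N = 8, J = 20, K = 4, seed = 33)
  fit <- quickFit(sim, "mmr_mammals", iterations = 1500, burnin = 500, seed = 17)
  # grid varying only the anthropogenic axis (raw values = center +/- 1 sd)
  sc <- scalingInfo(fit)$site
  raw <- cbind(
    elevation = rep(unname(sc$center["elevation"]), 2),
    forest = rep(unname(sc$center["forest"]), 2),
    anthropogenic = unname(sc$center["anthropogenic"]) +
      c(-1, 1) * unname(sc$scale["anthropogenic"])
  )
  grid <- applyScaling(covariateTable(raw, sites = c("low", "high")), sc)
  # restrict to draws where every species' anthropogenic coefficient is
  # negative: expected richness must then decline along that axis
  pooled <- posteriorDraws(fit)
  aCols <- grep("^alpha\\.anthropogenic\\[", colnames(pooled))
  keep <- rowSums(pooled[, aCols] >= 0) == 0
  expect_true(sum(keep) > 10)   # common under the strong negative hyper-mean
  sub <- fakeSamples(list(pooled[keep, , drop = FALSE]),
                     species = speciesIds(fit), sites = siteIds(fit),
                     spec = modelSpec(fit))
  pr <- predictRichness(sub, grid, ci = FALSE)
  expect_lt(pr$richness[2], pr$richness[1])

  badGrid <- covariateTable(cbind(elevation = 0, forest = 0), sites = "g")
  expect_error(predictRichness(fit, badGrid), "occupancy covariates")
})
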