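# Occupancy/detection submodels, marginal likelihood, priors, z conditional.

test_that("occupancy probabilities follow the logit-linear submodel", {
  covs <- standardizeCovariates(covariateTable(cbind(elevation = c(1, 2, 3))))
  st <- parameterState(u = c(0, 0),
                       alpha = matrix(c(1, 0), 2, 1,
                                      dimnames = list(NULL, "elevation")))
  psi <- occupancyProbability(st, covs)
  expect_equal(psi[2, ], rep(0.5, 3))                       # u = 0, alpha = 0
  expect_equal(psi[1, 2], 0.5)                              # covariate 0 at center
  expect_equal(psi[1, 3], plogis(covariateValues(covs)[3, 1]))

  # saturation without overflow
  stBig <- parameterState(u = 30)
  psiBig <- occupancyProbability(stBig, covariateTable(cbind(elevation = 1:3)[, 0, drop = FALSE]))
  expect_true(all(abs(psiBig - 1) < 1e-9))
  expect_true(all(psiBig < 1))

  bad <- covariateTable(cbind(elevation = c(1, NA, 3)))
  expect_error(occupancyProbability(st, bad), "non-finite")
})

test_that("detection probabilities broadcast site-level covariates over occasions", {
  J <- 2; K <- 3
  occ <- covariateTable(array(0, c(J, K, 1), dimnames = list(NULL, NULL, "date")),
                        "site_occasion")
  st <- parameterState(u = 0, v = 0,
                       beta = matrix(-0.472, 1, 1, dimnames = list(NULL, "date")))
  p0 <- detectionProbability(st, occ)
  expect_equal(as.vector(p0), rep(0.5, J * K))              # all covariates 0

  occ1 <- covariateTable(array(1, c(J, K, 1), dimnames = list(NULL, NULL, "date")),
                         "site_occasion")
  p1 <- detectionProbability(st, occ1)
  expect_equal(as.vector(p1), rep(plogis(-0.472), J * K))

  # site-level detection covariate replicated over k
  siteTab <- covariateTable(cbind(understory = c(0.5, -0.5)))
  stU <- parameterState(u = 0, v = 0,
                        beta = matrix(2, 1, 1, dimnames = list(NULL, "understory")))
  pU <- detectionProbability(stU, siteTab, K = 3)
  expect_equal(pU[1, 1, ], rep(plogis(2 * 0.5), 3))
  expect_equal(pU[1, 2, ], rep(plogis(-2 * 0.5), 3))

  expect_error(detectionProbability(st, siteTab, K = 3), "date")
})

test_that("marginal likelihood matches hand values and enumeration over z", {
  expect_equal(speciesSiteMarginalLik(c(0, 0), 0.5, c(0.5, 0.5)), 0.625)
  expect_equal(speciesSiteMarginalLik(c(1, 0), 0.5, c(0.5, 0.5)), 0.125)
  expect_equal(speciesSiteMarginalLik(c(0, 0), 0.5, c(0.5, 0.5), mask = c(0, 0)), 1)
  expect_error(speciesSiteMarginalLik(c(1, 0), 0.5, c(0.5, 0.5), mask = c(0, 1)),
               "unobserved")

  set.seed(101)
  for (rep in 1:200) {
    K <- sample(1:5, 1)
    psi <- runif(1, 0.01, 0.99)
    p <- runif(K, 0.01, 0.99)
    mask <- rbinom(K, 1, 0.8)
    history <- rbinom(K, 1, 0.5) * mask
    expect_equal(speciesSiteMarginalLik(history, psi, p, mask),
                 enumMarginalLik(history, psi, p, mask), tolerance = 1e-12)
  }
})

test_that("total log-likelihood composes cells and ignores missing data", {
  x <- array(0, c(1, 1, 2))
  dd <- detectionData(x)
  psi <- matrix(0.5, 1, 1)
  p <- array(0.5, c(1, 1, 2))
  expect_equal(totalLogLik(dd, psi, p), log(0.625))

  ddMiss <- detectionData(x, mask = matrix(0, 1, 2))
  expect_equal(totalLogLik(ddMiss, psi, p), 0)

  # N=3, J=4, K=2 random instance against the per-cell enumeration oracle
  set.seed(31)
  N <- 3; J <- 4; K <- 2
  mask <- matrix(rbinom(J * K, 1, 0.8), J, K)
  x <- array(rbinom(N * J * K, 1, 0.3), c(N, J, K))
  dd <- detectionData(x, mask)
  psi <- matrix(runif(N * J, 0.05, 0.95), N, J)
  p <- array(runif(N * J * K, 0.05, 0.95), c(N, J, K))
  oracle <- 0
  for (i in 1:N) for (j in 1:J) {
    if (sum(mask[j, ]) == 0) next
    oracle <- oracle + log(enumMarginalLik(detectionArray(dd)[i, j, ],
                                           psi[i, j], p[i, j, ], mask[j, ]))
  }
  expect_equal(totalLogLik(dd, psi, p), oracle, tolerance = 1e-10)

  # invariance under permuting species and sites
  pi <- sample(N); pj <- sample(J)
  dd2 <- detectionData(x[pi, pj, , drop = FALSE], mask[pj, , drop = FALSE])
  expect_equal(totalLogLik(dd2, psi[pi, pj], p[pi, pj, , drop = FALSE]),
               totalLogLik(dd, psi, p), tolerance = 1e-12)
})

test_that("log prior sums family densities and enforces the sd support", {
  spec <- ModelSpec(occupancyCovariates = "forest")
  stMode <- parameterState(u = c(0.3, 0.3), v = c(-0.1, -0.1),
                           alpha = matrix(1.5, 2, 1, dimnames = list(NULL, "forest")),
                           muU = 0.3, muV = -0.1, sigmaU = 1, sigmaV = 1,
                           muAlpha = c(forest = 1.5), sigmaAlpha = c(forest = 1))
  # every species effect sits at its hyper-mean: each contributes the mode density
  lp <- logPrior(stMode, spec)
  expected <- 6 * dnorm(0, 0, 1, log = TRUE) +
    dnorm(0.3, 0, 2.25, log = TRUE) + dnorm(-0.1, 0, 2.25, log = TRUE) +
    dnorm(1.5, 0, 2.25, log = TRUE) + 3 * dunif(1, 0, 5, log = TRUE)
  expect_equal(lp, expected, tolerance = 1e-10)

  stBad <- stMode
  stBad@sigmaU <- 6
  expect_equal(logPrior(stBad, spec), -Inf)

  # random state against a term-by-term oracle
  set.seed(55)
  st <- parameterState(u = rnorm(3), v = rnorm(3),
                       alpha = matrix(rnorm(3), 3, 1, dimnames = list(NULL, "forest")),
                       muU = rnorm(1), muV = rnorm(1),
                       sigmaU = runif(1, 0.5, 4), sigmaV = runif(1, 0.5, 4),
                       muAlpha = c(forest = rnorm(1)),
                       sigmaAlpha = c(forest = runif(1, 0.5, 4)))
  oracle <- sum(dnorm(st@u, st@muU, st@sigmaU, log = TRUE)) +
    sum(dnorm(st@v, st@muV, st@sigmaV, log = TRUE)) +
    sum(dnorm(st@alpha[, 1], st@muAlpha, st@sigmaAlpha, log = TRUE)) +
    sum(dnorm(c(st@muU, st@muV, st@muAlpha), 0, 2.25, log = TRUE)) +
    3 * dunif(1, 0, 5, log = TRUE)
  expect_equal(logPrior(st, spec), oracle, tolerance = 1e-10)
})

test_that("z full conditional is exact and has the right limits", {
  expect_equal(zFullConditional(c(1, 0), 0.5, c(0.5, 0.5)), 1)
  expect_equal(zFullConditional(0, 0.5, 0.5), 1 / 3)
  expect_equal(zFullConditional(c(0, 0), 0.5, c(0.5, 0.5)), 0.2)
  # no-information limit: p -> 0 gives psi
  expect_equal(zFullConditional(rep(0, 3), 0.7, rep(1e-12, 3)), 0.7,
               tolerance = 1e-9)
  # strong-information limit: many failed occasions drive z toward 0
  expect_lt(zFullConditional(rep(0, 50), 0.7, rep(0.5, 50)), 1e-10)
})

test_that("probabilities from finite predictors never reach exactly 0 or 1", {
  st <- parameterState(u = c(-1000, 1000))
  psi <- occupancyProbability(st, covariateTable(matrix(0, 3, 0)))
  expect_true(all(psi > 0 & psi < 1))
})
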