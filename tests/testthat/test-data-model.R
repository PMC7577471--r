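# Detection-history containers, I/O and covariate preparation.

test_that("detection records encode, mask and round-trip correctly", {
  # direct encoding: 1 species, 1 site, occasions (1,2), detected (0,1)
  tmp <- withr::local_tempdir()
  rec <- data.frame(species = "a", site = "s1", occasion = c("o1", "o2"),
                    detected = c(0, 1))
  write.csv(rec, file.path(tmp, "rec.csv"), row.names = FALSE)
  dd <- readDetectionRecords(file.path(tmp, "rec.csv"))
  expect_equal(dim(detectionArray(dd)), c(1, 1, 2))
  expect_equal(as.vector(detectionArray(dd)), c(0, 1))
  expect_true(all(observedMask(dd) == 1))

  # occasions absent from the manifest are not surveyed; records there ignored
  man <- data.frame(site = "s1", occasion = c("o1", "o2"))
  rec3 <- rbind(rec, data.frame(species = "a", site = "s1", occasion = "o3",
                                detected = 1))
  write.csv(rec3, file.path(tmp, "rec3.csv"), row.names = FALSE)
  dd3 <- readDetectionRecords(file.path(tmp, "rec3.csv"), man)
  expect_equal(occasionIds(dd3), c("o1", "o2", "o3"))
  expect_equal(observedMask(dd3)[1, ], c(1, 1, 0))
  expect_equal(detectionArray(dd3)[1, 1, 3], 0)   # record ignored under mask

  # lossless round-trip through write + read
  sim <- smallSim(N = 4, J = 6, K = 3, seed = 3, missingRate = 0.2)
  fr <- file.path(tmp, "round.csv"); fm <- file.path(tmp, "round_man.csv")
  writeDetectionRecords(sim$data, fr, fm)
  back <- readDetectionRecords(fr, fm)
  expect_equal(detectionArray(back), detectionArray(sim$data))
  expect_equal(observedMask(back), observedMask(sim$data))
  expect_equal(detectionCounts(back), detectionCounts(sim$data))
})

test_that("malformed detection records are rejected", {
  tmp <- withr::local_tempdir()
  bad <- data.frame(species = "a", site = "s1", occasion = c("o1", "o1"),
                    detected = c(0, 1))
  write.csv(bad, file.path(tmp, "bad.csv"), row.names = FALSE)
  expect_error(readDetectionRecords(file.path(tmp, "bad.csv")), "conflicting")
  bad2 <- data.frame(species = "a", site = "s1", occasion = "o1", detected = 2)
  write.csv(bad2, file.path(tmp, "bad2.csv"), row.names = FALSE)
  expect_error(readDetectionRecords(file.path(tmp, "bad2.csv")), "0 or 1")
})

test_that("standardization centers, scales, inverts and is idempotent", {
  tab <- covariateTable(cbind(a = c(1, 2, 3), b = c(10, 20, 30, 40)[1:3]))
  std <- standardizeCovariates(tab)
  expect_equal(covariateValues(std)[, 1], c(-1, 0, 1))   # sample sd of (1,2,3) is 1
  expect_true(isStandardized(std))

  tab4 <- covariateTable(cbind(b = c(10, 20, 30, 40)))
  std4 <- standardizeCovariates(tab4)
  expect_equal(mean(covariateValues(std4)), 0)
  expect_equal(sd(covariateValues(std4)), 1)
  expect_equal(covariateValues(unstandardizeCovariates(std4)),
               covariateValues(tab4))

  # idempotence: re-standardizing changes nothing (to 1e-9) and the
  # composed scaling still recovers the raw values
  again <- standardizeCovariates(std4)
  expect_equal(covariateValues(again), covariateValues(std4), tolerance = 1e-9)
  expect_equal(covariateValues(unstandardizeCovariates(again)),
               covariateValues(tab4))

  const <- covariateTable(cbind(flat = rep(5, 4)))
  expect_error(standardizeCovariates(const), "flat")
})

test_that("collinearity screening drops by the r- and VIF-rules", {
  # exactly orthogonal covariates: both retained with VIF 1
  orth <- covariateTable(cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1)))
  rep1 <- screenCollinearity(orth)
  expect_setequal(rep1$retained, c("a", "b"))
  expect_equal(unname(rep1$vif[c("a", "b")]), c(1, 1))

  # duplicated covariate: one dropped by the r-rule
  set.seed(4)
  xa <- rnorm(20)
  dup <- covariateTable(cbind(a = xa, b = xa, c = rnorm(20)))
  rep2 <- screenCollinearity(dup)
  expect_equal(nrow(rep2$dropped), 1L)
  expect_equal(rep2$dropped$reason, "r-rule")
  expect_true("c" %in% rep2$retained)

  # VIFs match an independent least-squares oracle (normal equations)
  set.seed(11)
  c1 <- rnorm(50); c2 <- rnorm(50)
  c3 <- 0.9 * c1 + rnorm(50, sd = 0.5)
  m <- cbind(c1 = c1, c2 = c2, c3 = c3)
  rep3 <- screenCollinearity(covariateTable(m), rMax = 0.99, vifMax = 1e6)
  oracleVif <- sapply(colnames(m), function(nm) {
    y <- m[, nm]; X <- cbind(1, m[, setdiff(colnames(m), nm)])
    bh <- solve(t(X) %*% X, t(X) %*% y)
    r2 <- 1 - sum((y - X %*% bh)^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  })
  expect_equal(rep3$vif[colnames(m)], oracleVif, tolerance = 1e-8)

  expect_error(screenCollinearity(covariateTable(matrix(rnorm(6), 2, 3))),
               "at least 3")
  expect_error(screenCollinearity(covariateTable(matrix(rnorm(12), 3, 4))),
               "fewer rows")
})

test_that("screening output always satisfies both thresholds", {
  for (seed in 1:5) {
    set.seed(seed)
    base <- matrix(rnorm(40 * 3), 40, 3)
    m <- cbind(base,
               base[, 1] * 0.95 + rnorm(40, sd = 0.2),
               base[, 2] + base[, 3])
    colnames(m) <- paste0("c", 1:5)
    rep <- screenCollinearity(covariateTable(m))
    kept <- m[, rep$retained, drop = FALSE]
    if (length(rep$retained) >= 2) {
      r <- cor(kept)
      expect_true(all(abs(r[row(r) != col(r)]) <= 0.60))
      expect_true(all(rep$vif[rep$retained] <= 3))
    }
    expect_setequal(c(rep$retained, rep$dropped$name), colnames(m))
  }
})

test_that("habitat pooling is additive and conserves cover", {
  cols <- c("semi_evergreen_forest", "moist_deciduous_forest", "mangrove",
            "scrub_forest", "grassland", "settlement", "agriculture")
  m <- rbind(c(0.1, 0.2, 0.0, 0.3, 0.1, 0.2, 0.1), rep(0, 7))
  colnames(m) <- cols
  pooled <- poolHabitatCovers(covariateTable(m))
  expect_equal(unname(covariateValues(pooled)[1, ]), c(0.3, 0.4, 0.3))
  expect_equal(unname(covariateValues(pooled)[2, ]), c(0, 0, 0))

  set.seed(21)
  mr <- matrix(runif(35 * 7), 35, 7, dimnames = list(NULL, cols))
  mr <- mr / rowSums(mr)
  pr <- poolHabitatCovers(covariateTable(mr))
  expect_equal(rowSums(covariateValues(pr)), rowSums(mr), tolerance = 1e-12)

  expect_error(poolHabitatCovers(covariateTable(mr[, -3])), "mangrove")

  cls <- habitatClasses(pr)
  expect_s3_class(cls, "HabitatClassTable")
  expect_equal(nrow(cls), 35)
  expect_true(all(cls$class %in% c("forest", "degraded_forest", "anthropogenic")))
})

test_that("detection counts and naive occupancy summarize the history", {
  # species detected on 13 observed cells spread over 5 of 35 sites
  x <- array(0, c(2, 35, 6))
  hits <- cbind(site = c(1, 1, 1, 2, 2, 3, 3, 3, 4, 4, 5, 5, 5),
                occ = c(1, 2, 3, 1, 2, 1, 2, 4, 3, 5, 1, 2, 6))
  for (r in seq_len(nrow(hits))) x[1, hits[r, 1], hits[r, 2]] <- 1
  dd <- detectionData(x)
  counts <- detectionCounts(dd)
  expect_equal(counts$detections, c(13L, 0L))
  expect_equal(counts$sitesWithDetection, c(5L, 0L))
  nocc <- naiveOccupancy(dd)
  expect_equal(unname(nocc), c(5 / 35, 0))

  allone <- detectionData(array(1, c(1, 4, 2)))
  expect_equal(unname(naiveOccupancy(allone)), 1)
})

test_that("observed richness counts detected species per group", {
  x <- array(0, c(3, 4, 2))
  x[1, 1, 1] <- 1          # species 1 only at site 1
  x[2, 1, 2] <- 1          # species 2 also at site 1
  dd <- detectionData(x)
  rich <- observedRichness(dd)
  expect_equal(unname(rich), c(2L, 0L, 0L, 0L))

  grouping <- setNames(c("g1", "g1", "g2", "g2"), siteIds(dd))
  expect_equal(unname(observedRichness(dd, grouping)), c(2L, 0L))
  expect_error(observedRichness(dd, grouping[-1]), "lacks site")

  # enumeration oracle on a synthetic community
  sim <- smallSim(N = 8, J = 10, K = 3, seed = 17)
  dd <- sim$data
  rich <- observedRichness(dd)
  for (j in seq_along(siteIds(dd))) {
    brute <- sum(vapply(seq_along(speciesIds(dd)), function(i)
      any(detectionArray(dd)[i, j, ] == 1), logical(1)))
    expect_identical(unname(rich[j]), as.integer(brute))
  }
  expect_true(all(rich <= length(speciesIds(dd))))
})

test_that("covariate tables round-trip through CSV at both levels", {
  tmp <- withr::local_tempdir()
  sim <- smallSim(N = 3, J = 5, K = 3, seed = 9)
  fs <- file.path(tmp, "site.csv")
  writeCovariateTable(sim$covariates$site, fs)
  backS <- readCovariateTable(fs, "site")
  expect_equal(covariateValues(backS), covariateValues(sim$covariates$site),
               tolerance = 1e-12)
  expect_equal(covariateNames(backS), covariateNames(sim$covariates$site))

  fo <- file.path(tmp, "occ.csv")
  writeCovariateTable(sim$covariates$occasion, fo)
  backO <- readCovariateTable(fo, "site_occasion")
  expect_equal(covariateValues(backO), covariateValues(sim$covariates$occasion),
               tolerance = 1e-12)
})
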