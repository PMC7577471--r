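# Metropolis-within-Gibbs sampler for the multi-species occupancy model.
#
# Update scheme per iteration:
#   1. latent occupancy z: exact Bernoulli full conditional (data
#      augmentation); z is forced to 1 wherever a detection exists;
#   2. species occupancy effects (u_i, alpha_i) and detection effects
#      (v_i, beta_i): random-walk Metropolis, one effect family at a time,
#      as N independent scalar updates (species are conditionally
#      independent given z and the hyper-parameters);
#   3. community hyper-means: conjugate normal Gibbs draws;
#   4. community hyper-sds: random-walk Metropolis on the log scale with
#      the Uniform(0, upper) prior and log-scale Jacobian.
# Proposal scales adapt by Robbins-Monro toward 0.44 acceptance and are
# frozen after `adaptUntil` (default: end of burn-in), so retained draws
# come from a fixed transition kernel.
#
# Two engines share this scheme: the compiled chain (src/chain.cpp, the
# default) and a plain-R reference implementation. They follow the same
# update order and the same R-RNG call sequence, so a given seed yields
# identical draws from either engine; the test suite checks this.

#' Create an MCMC configuration
#'
#' Defaults follow the long-run protocol used for the full analyses:
#' 3 chains of 150000 iterations, burn-in 50000, thinning 100, which
#' retains 3000 draws in total.
#'
#' @param chains,iterations,burnin,thin run-length settings.
#' @param baseSeed integer seed; chain c uses a seed derived from
#'   \code{baseSeed} and c, so identical configurations reproduce draws
#'   bit-exactly.
#' @param adaptUntil iteration after which proposal adaptation stops;
#'   defaults to \code{burnin}.
#' @param storeZ store thinned latent-occupancy draws (needed for
#'   \code{\link{estimatedRichness}}).
#' @return a validated \code{\linkS4class{McmcConfig}}.
#' @export
McmcConfig <- function(chains = 3L, iterations = 150000L, burnin = 50000L,
                       thin = 100L, baseSeed = 1L, adaptUntil = NULL,
                       storeZ = TRUE) {
  new("McmcConfig",
    chains = as.integer(chains), iterations = as.integer(iterations),
    burnin = as.integer(burnin), thin = as.integer(thin),
    baseSeed = as.integer(baseSeed),
    adaptUntil = as.integer(adaptUntil %||% burnin),
    storeZ = isTRUE(storeZ)
  )
}

#' Fit the multi-species occupancy model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler described in the package
#' vignette. Covariate tables must already be standardized (and, where
#' appropriate, screened for collinearity).
#'
#' @param data a \code{DetectionData} with at least one detection.
#' @param siteCovariates standardized site-level \code{CovariateTable}
#'   (or NULL for intercept-only occupancy).
#' @param occasionCovariates optional standardized occasion-level
#'   \code{CovariateTable}; site-level detection covariates are looked up
#'   in \code{siteCovariates} and broadcast over occasions.
#' @param spec a \code{ModelSpec}.
#' @param config a \code{McmcConfig}.
#' @param engine \code{"cpp"} (compiled chain, default) or \code{"R"}
#'   (reference implementation; identical draws, much slower).
#' @return a \code{\linkS4class{PosteriorSamples}}.
#' @export
runMcmc <- function(data, siteCovariates = NULL, occasionCovariates = NULL,
                    spec = ModelSpec(), config = McmcConfig(),
                    engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (sum(data@x) == 0) {
    stop("no detections at all: the detection submodel is unidentified")
  }
  for (tab in list(siteCovariates, occasionCovariates)) {
    if (!is.null(tab) && !tab@standardized) {
      stop("covariate tables must be standardized before fitting")
    }
  }
  if (is.null(siteCovariates) && length(spec@occupancyCovariates)) {
    stop("occupancy covariates named in the spec but no site table supplied")
  }
  d <- dim(data@x)
  N <- d[1L]; J <- d[2L]; K <- d[3L]
  X <- if (is.null(siteCovariates)) {
    matrix(0, J, 0L)
  } else {
    occupancyDesign(spec@occupancyCovariates, siteCovariates)
  }
  W <- detectionDesign(spec@detectionCovariates,
                       list(occasionCovariates, siteCovariates), J, K)
  prep <- list(
    N = N, J = J, K = K, M = J * K,
    x = matrix(data@x, N, J * K),
    maskv = as.numeric(data@mask),
    detAny = (rowSums(array(data@x, d), dims = 2L) > 0) * 1,
    X = X, W = W, sidx = rep(seq_len(J), K)
  )
  scaling <- list()
  if (!is.null(siteCovariates)) scaling$site <- scalingInfo(siteCovariates)
  if (!is.null(occasionCovariates)) scaling$occasion <- scalingInfo(occasionCovariates)

  chains <- vector("list", config@chains)
  zChains <- vector("list", config@chains)
  accAll <- NULL
  for (ch in seq_len(config@chains)) {
    res <- runChain(prep, spec, config, deriveSeed(config@baseSeed, ch), engine)
    chains[[ch]] <- res$draws
    zChains[[ch]] <- res$z
    accAll <- if (is.null(accAll)) res$acceptance else accAll + res$acceptance
  }
  accAll <- accAll / config@chains
  new("PosteriorSamples",
    draws = chains,
    zDraws = if (config@storeZ) zChains else list(),
    config = config, modelSpec = spec,
    species = data@species, sites = data@sites,
    scaling = scaling, acceptance = accAll
  )
}

# Shared per-chain setup (initial values, family bookkeeping, parameter
# names), then dispatch to the compiled or the reference engine.
runChain <- function(prep, spec, config, seed, engine = "cpp") {
  N <- prep$N; J <- prep$J; M <- prep$M
  Cocc <- ncol(prep$X); Cdet <- ncol(prep$W)
  occNames <- colnames(prep$X); detNames <- colnames(prep$W)
  families <- c("u", "v",
                if (Cocc) paste0("alpha.", occNames),
                if (Cdet) paste0("beta.", detNames))
  fixedMu <- spec@fixedHyperMean
  fixedSd <- spec@fixedHyperSd
  isFixed <- vapply(families, function(f)
    f %in% names(fixedMu) && f %in% names(fixedSd), logical(1))

  # moment-based starting values on the logit scale
  detPerSpecies <- rowSums(prep$x * matrix(rep(prep$maskv, each = N), N, M))
  sitesDet <- rowSums(matrix(prep$detAny, N, J))
  obsCells <- sum(prep$maskv)
  u0 <- stats::qlogis(pmin(pmax(sitesDet / J, 1 / (2 * J)), 1 - 1 / (2 * J)))
  v0 <- stats::qlogis(pmin(pmax(detPerSpecies / obsCells, 1 / (2 * obsCells)),
                           1 - 1 / (2 * obsCells)))
  hyperMu0 <- stats::setNames(numeric(length(families)), families)
  hyperSd0 <- stats::setNames(rep(1, length(families)), families)
  hyperMu0["u"] <- mean(u0); hyperMu0["v"] <- mean(v0)
  hyperMu0[names(fixedMu)[names(fixedMu) %in% families]] <-
    fixedMu[names(fixedMu) %in% families]
  hyperSd0[names(fixedSd)[names(fixedSd) %in% families]] <-
    fixedSd[names(fixedSd) %in% families]
  if (!all(is.finite(c(u0, v0, hyperMu0, hyperSd0)))) {
    stop("non-finite initial log posterior: check covariates and starting values")
  }

  parNames <- c(paste0("u[", seq_len(N), "]"), paste0("v[", seq_len(N), "]"),
                if (Cocc) as.vector(outer(seq_len(N), occNames,
                  function(i, c) paste0("alpha.", c, "[", i, "]"))),
                if (Cdet) as.vector(outer(seq_len(N), detNames,
                  function(i, c) paste0("beta.", c, "[", i, "]"))),
                paste0("mu.", families), paste0("sigma.", families))
  nRet <- as.integer(floor((config@iterations - config@burnin) / config@thin))

  set.seed(seed)
  res <- if (engine == "cpp") {
    .chainCpp(prep$x, prep$maskv, matrix(prep$detAny, N, J), prep$X, prep$W,
              u0, v0, unname(hyperMu0), unname(hyperSd0), unname(isFixed),
              spec@hyperMeanPriorSD, spec@hyperSdUpper,
              config@iterations, config@burnin, config@thin,
              config@adaptUntil, config@storeZ)
  } else {
    runChainR(prep, u0, v0, hyperMu0, hyperSd0, isFixed, families,
              spec, config, nRet)
  }
  draws <- res$draws
  colnames(draws) <- parNames
  acc <- ifelse(res$accTotal > 0, res$accCount / pmax(res$accTotal, 1), NA_real_)
  names(acc) <- c(families, paste0("sigma.", families))
  list(
    draws = draws,
    z = if (config@storeZ) array(res$z, c(N, J, nRet)) else NULL,
    acceptance = acc
  )
}

# Reference engine in plain R; mirrors src/chain.cpp step for step.
runChainR <- function(prep, u, v, hyperMu, hyperSd, isFixed, families,
                      spec, config, nRet) {
  N <- prep$N; J <- prep$J; M <- prep$M
  x <- prep$x
  maskM <- matrix(rep(prep$maskv, each = N), N, M)
  X <- prep$X; W <- prep$W; sidx <- prep$sidx
  Cocc <- ncol(X); Cdet <- ncol(W)
  occNames <- colnames(X); detNames <- colnames(W)
  tau <- spec@hyperMeanPriorSD
  sdUpper <- spec@hyperSdUpper

  alpha <- matrix(0, N, Cocc, dimnames = list(NULL, occNames))
  beta <- matrix(0, N, Cdet, dimnames = list(NULL, detNames))
  z <- matrix(1, N, J)
  etaPsi <- matrix(u, N, J) + if (Cocc) alpha %*% t(X) else 0
  etaP <- matrix(v, N, M) + if (Cdet) beta %*% t(W) else 0

  scales <- lapply(families, function(f) rep(0.5, N))
  names(scales) <- families
  sdScales <- stats::setNames(rep(0.5, length(families)), families)

  llOcc <- function(eta) {
    eta <- clipEta(eta)
    rowSums(z * eta - log1pexp(eta))
  }
  llDet <- function(eta, O) {
    eta <- clipEta(eta)
    rowSums(O * (x * eta - log1pexp(eta)))
  }

  draws <- matrix(NA_real_, nRet, N * (2 + Cocc + Cdet) + 2 * length(families))
  zDraws <- if (config@storeZ) array(NA_real_, c(N, J, nRet)) else NULL
  accCount <- accTotal <- stats::setNames(rep(0, 2 * length(families)),
                                          c(families, paste0("sigma.", families)))
  detAnyMat <- matrix(prep$detAny, N, J)

  for (t in seq_len(config@iterations)) {
    adapting <- t <= config@adaptUntil
    gamma <- if (adapting) min(0.25, 1 / sqrt(t)) else 0
    tracking <- t > config@burnin

    # ---- z: exact Bernoulli full conditional -------------------------------
    psi <- invLogit(etaPsi)
    logNoDet <- rowSums(array(maskM * -log1pexp(clipEta(etaP)), c(N, J, prep$K)),
                        dims = 2L)
    q <- psi * exp(logNoDet)
    probZ <- q / (q + 1 - psi)
    z <- (detAnyMat > 0) | (matrix(stats::runif(N * J), N, J) < probZ)
    storage.mode(z) <- "double"

    # ---- occupancy effects --------------------------------------------------
    llPsiCur <- llOcc(etaPsi)
    updOcc <- function(fam, cur, mult) {
      delta <- stats::rnorm(N) * scales[[fam]]
      etaNew <- etaPsi + if (is.null(mult)) delta else outer(delta, mult)
      llNew <- llOcc(etaNew)
      lpDiff <- stats::dnorm(cur + delta, hyperMu[fam], hyperSd[fam], log = TRUE) -
        stats::dnorm(cur, hyperMu[fam], hyperSd[fam], log = TRUE)
      acc <- log(stats::runif(N)) < (llNew - llPsiCur + lpDiff)
      if (any(acc)) {
        etaPsi[acc, ] <<- etaNew[acc, , drop = FALSE]
        llPsiCur[acc] <<- llNew[acc]
        cur[acc] <- cur[acc] + delta[acc]
      }
      if (adapting) scales[[fam]] <<- scales[[fam]] * exp(gamma * (acc - 0.44))
      if (tracking) {
        accCount[fam] <<- accCount[fam] + sum(acc)
        accTotal[fam] <<- accTotal[fam] + N
      }
      cur
    }
    u <- updOcc("u", u, NULL)
    for (ci in seq_len(Cocc)) {
      alpha[, ci] <- updOcc(paste0("alpha.", occNames[ci]), alpha[, ci], X[, ci])
    }

    # ---- detection effects --------------------------------------------------
    O <- maskM * z[, sidx]
    llDetCur <- llDet(etaP, O)
    updDet <- function(fam, cur, mult) {
      delta <- stats::rnorm(N) * scales[[fam]]
      etaNew <- etaP + if (is.null(mult)) delta else outer(delta, mult)
      llNew <- llDet(etaNew, O)
      lpDiff <- stats::dnorm(cur + delta, hyperMu[fam], hyperSd[fam], log = TRUE) -
        stats::dnorm(cur, hyperMu[fam], hyperSd[fam], log = TRUE)
      acc <- log(stats::runif(N)) < (llNew - llDetCur + lpDiff)
      if (any(acc)) {
        etaP[acc, ] <<- etaNew[acc, , drop = FALSE]
        llDetCur[acc] <<- llNew[acc]
        cur[acc] <- cur[acc] + delta[acc]
      }
      if (adapting) scales[[fam]] <<- scales[[fam]] * exp(gamma * (acc - 0.44))
      if (tracking) {
        accCount[fam] <<- accCount[fam] + sum(acc)
        accTotal[fam] <<- accTotal[fam] + N
      }
      cur
    }
    v <- updDet("v", v, NULL)
    for (ci in seq_len(Cdet)) {
      beta[, ci] <- updDet(paste0("beta.", detNames[ci]), beta[, ci], W[, ci])
    }

    # ---- hyper-parameters ---------------------------------------------------
    for (fi in seq_along(families)) {
      if (isFixed[fi]) next
      f <- families[fi]
      vals <- switch(substr(f, 1, 1),
        u = u, v = v,
        a = alpha[, sub("^alpha\\.", "", f)],
        b = beta[, sub("^beta\\.", "", f)]
      )
      prec <- N / hyperSd[f]^2 + 1 / tau^2
      hyperMu[f] <- stats::rnorm(1, (sum(vals) / hyperSd[f]^2) / prec,
                                 sqrt(1 / prec))
      sNew <- hyperSd[f] * exp(stats::rnorm(1) * sdScales[f])
      accepted <- FALSE
      if (sNew < sdUpper) {
        logr <- sum(stats::dnorm(vals, hyperMu[f], sNew, log = TRUE)) -
          sum(stats::dnorm(vals, hyperMu[f], hyperSd[f], log = TRUE)) +
          log(sNew) - log(hyperSd[f])
        if (log(stats::runif(1)) < logr) {
          hyperSd[f] <- sNew
          accepted <- TRUE
        }
      } else {
        stats::runif(1)   # keep the RNG stream aligned across accept paths
      }
      sf <- paste0("sigma.", f)
      if (adapting) sdScales[f] <- sdScales[f] * exp(gamma * (accepted - 0.44))
      if (tracking) {
        accCount[sf] <- accCount[sf] + accepted
        accTotal[sf] <- accTotal[sf] + 1
      }
    }

    # ---- record -------------------------------------------------------------
    if (t > config@burnin && (t - config@burnin) %% config@thin == 0L) {
      r <- (t - config@burnin) %/% config@thin
      draws[r, ] <- c(u, v,
                      if (Cocc) as.vector(alpha), if (Cdet) as.vector(beta),
                      hyperMu[families], hyperSd[families])
      if (config@storeZ) zDraws[, , r] <- z
    }
  }

  list(draws = draws, z = zDraws, accCount = accCount, accTotal = accTotal)
}

# Rebuild a ParameterState from one row of pooled draws (no z).
stateFromRow <- function(row, N, spec) {
  occNames <- spec@occupancyCovariates
  detNames <- spec@detectionCovariates
  pick <- function(stub) unname(row[paste0(stub, "[", seq_len(N), "]")])
  alpha <- matrix(0, N, length(occNames), dimnames = list(NULL, occNames))
  for (nm in occNames) alpha[, nm] <- pick(paste0("alpha.", nm))
  beta <- matrix(0, N, length(detNames), dimnames = list(NULL, detNames))
  for (nm in detNames) beta[, nm] <- pick(paste0("beta.", nm))
  parameterState(
    u = pick("u"), v = pick("v"), alpha = alpha, beta = beta,
    muU = unname(row["mu.u"]), muV = unname(row["mu.v"]),
    sigmaU = unname(row["sigma.u"]), sigmaV = unname(row["sigma.v"]),
    muAlpha = stats::setNames(row[paste0("mu.alpha.", occNames)], occNames),
    muBeta = stats::setNames(row[paste0("mu.beta.", detNames)], detNames),
    sigmaAlpha = stats::setNames(row[paste0("sigma.alpha.", occNames)], occNames),
    sigmaBeta = stats::setNames(row[paste0("sigma.beta.", detNames)], detNames)
  )
}
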