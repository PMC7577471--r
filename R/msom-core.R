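# The hierarchical model: logit-linear occupancy and detection submodels,
# community hyper-distributions, priors, and the marginal likelihood of a
# detection history with the latent occupancy state summed out.

#' Create a model specification
#'
#' @param occupancyCovariates ordered character vector of covariate names
#'   entering the occupancy submodel (may be empty for intercept-only).
#' @param detectionCovariates ordered character vector for the detection
#'   submodel; the set may differ between datasets.
#' @param hyperMeanPriorSD sd of the Normal(0, sd) prior on community
#'   hyper-means (logit scale); default 2.25, weakly informative (close to
#'   uniform on the probability scale after the inverse logit).
#' @param hyperSdUpper upper bound of the Uniform(0, upper) prior on
#'   community hyper-sds; default 5.
#' @param fixedHyperMean,fixedHyperSd optional named numeric vectors fixing
#'   hyper-parameters of effect families (\code{"u"}, \code{"v"},
#'   \code{"alpha.<cov>"}, \code{"beta.<cov>"}); fixed families are not
#'   updated during sampling.
#' @return a \code{\linkS4class{ModelSpec}}.
#' @export
ModelSpec <- function(occupancyCovariates = character(),
                      detectionCovariates = character(),
                      hyperMeanPriorSD = 2.25,
                      hyperSdUpper = 5,
                      fixedHyperMean = numeric(),
                      fixedHyperSd = numeric()) {
  new("ModelSpec",
    occupancyCovariates = as.character(occupancyCovariates),
    detectionCovariates = as.character(detectionCovariates),
    hyperMeanPriorSD = hyperMeanPriorSD,
    hyperSdUpper = hyperSdUpper,
    fixedHyperMean = fixedHyperMean,
    fixedHyperSd = fixedHyperSd
  )
}

#' Create a parameter state
#'
#' Bundles one full state of the model's latent quantities. Coefficient
#' matrices default to zero columns for intercept-only submodels.
#'
#' @param u,v species-level occupancy/detection intercepts (length N).
#' @param alpha,beta N x C species coefficient matrices with named columns.
#' @param muU,muV,sigmaU,sigmaV intercept-family hyper-parameters.
#' @param muAlpha,muBeta,sigmaAlpha,sigmaBeta named per-covariate
#'   hyper-parameters.
#' @param z binary N x J latent occupancy matrix (may be 0 x 0 when not
#'   needed, e.g. for probability evaluation).
#' @return a \code{\linkS4class{ParameterState}}.
#' @export
parameterState <- function(u, v = numeric(length(u)),
                           alpha = matrix(0, length(u), 0L),
                           beta = matrix(0, length(u), 0L),
                           muU = 0, muV = 0, sigmaU = 1, sigmaV = 1,
                           muAlpha = numeric(), muBeta = numeric(),
                           sigmaAlpha = numeric(), sigmaBeta = numeric(),
                           z = matrix(0, 0L, 0L)) {
  if (length(sigmaAlpha) == 0L && ncol(alpha) > 0L) {
    sigmaAlpha <- stats::setNames(rep(1, ncol(alpha)), colnames(alpha))
  }
  if (length(sigmaBeta) == 0L && ncol(beta) > 0L) {
    sigmaBeta <- stats::setNames(rep(1, ncol(beta)), colnames(beta))
  }
  if (length(muAlpha) == 0L && ncol(alpha) > 0L) {
    muAlpha <- stats::setNames(rep(0, ncol(alpha)), colnames(alpha))
  }
  if (length(muBeta) == 0L && ncol(beta) > 0L) {
    muBeta <- stats::setNames(rep(0, ncol(beta)), colnames(beta))
  }
  new("ParameterState",
    u = u, v = v, alpha = alpha, beta = beta,
    muU = muU, muV = muV, sigmaU = sigmaU, sigmaV = sigmaV,
    muAlpha = muAlpha, muBeta = muBeta,
    sigmaAlpha = sigmaAlpha, sigmaBeta = sigmaBeta, z = z
  )
}

# J x C occupancy design matrix in the column order of the coefficient
# matrix; rejects missing names and non-finite values.
occupancyDesign <- function(covNames, siteCovs) {
  if (!length(covNames)) {
    return(matrix(0, length(siteCovs@sites), 0L))
  }
  missing <- setdiff(covNames, siteCovs@covariates)
  if (length(missing)) {
    stop("occupancy covariate(s) absent from table: ", paste(missing, collapse = ", "))
  }
  X <- siteCovs@values[, match(covNames, siteCovs@covariates), drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite occupancy covariate value")
  colnames(X) <- covNames
  X
}

# (J*K) x C detection design matrix: occasion-level covariates are taken
# from a site_occasion table, site-level detection covariates (e.g.
# understory height, wood stem density) broadcast over occasions. Columns
# of the flattened matrix are ordered site-fastest ((k-1)*J + j).
detectionDesign <- function(covNames, covariates, J, K) {
  if (!is.list(covariates)) covariates <- list(covariates)
  M <- J * K
  W <- matrix(0, M, length(covNames))
  colnames(W) <- covNames
  for (ci in seq_along(covNames)) {
    nm <- covNames[ci]
    found <- FALSE
    for (tab in covariates) {
      if (is.null(tab) || !nm %in% tab@covariates) next
      col <- covariateColumn(tab, nm)
      if (tab@level == "site_occasion") {
        if (!all(dim(col) == c(J, K))) stop("dimension mismatch for covariate '", nm, "'")
        W[, ci] <- as.numeric(col)
      } else {
        if (length(col) != J) stop("dimension mismatch for covariate '", nm, "'")
        W[, ci] <- rep(col, K)
      }
      found <- TRUE
      break
    }
    if (!found) stop("detection covariate '", nm, "' absent from supplied tables")
  }
  if (!all(is.finite(W))) stop("non-finite detection covariate value")
  W
}

#' Occupancy probabilities for one parameter state
#'
#' Evaluates \code{psi[i, j] = invLogit(u_i + sum_c alpha[i, c] * cov[j, c])}
#' for all species and sites. Values are strictly inside (0, 1).
#'
#' @param state a \code{ParameterState}.
#' @param siteCovs standardized site-level \code{CovariateTable} holding the
#'   covariates named by \code{colnames(state@alpha)}.
#' @return numeric N x J matrix of occupancy probabilities.
#' @export
occupancyProbability <- function(state, siteCovs) {
  X <- occupancyDesign(colnames(state@alpha), siteCovs)
  eta <- state@u + if (ncol(X)) state@alpha %*% t(X) else
    matrix(0, length(state@u), nrow(X))
  invLogit(eta)
}

#' Detection probabilities for one parameter state
#'
#' Evaluates \code{p[i, j, k] = invLogit(v_i + sum_c beta[i, c] * w[j, k, c])}.
#' Site-level detection covariates are broadcast over occasions. The value
#' is computed for every cell; unobserved occasions are excluded from
#' likelihoods by the survey mask, not here.
#'
#' @param state a \code{ParameterState}.
#' @param covariates a \code{CovariateTable} or list of tables (site and/or
#'   site-occasion level) supplying the covariates named by
#'   \code{colnames(state@beta)}.
#' @param K number of occasions; inferred from an occasion-level table if
#'   absent.
#' @return numeric N x J x K array of detection probabilities.
#' @export
detectionProbability <- function(state, covariates, K = NULL) {
  tabs <- if (is.list(covariates)) covariates else list(covariates)
  tabs <- Filter(Negate(is.null), tabs)
  J <- length(tabs[[1L]]@sites)
  if (is.null(K)) {
    for (tab in tabs) if (tab@level == "site_occasion") K <- length(tab@occasions)
    if (is.null(K)) stop("K cannot be inferred: supply an occasion-level table or K")
  }
  W <- detectionDesign(colnames(state@beta), tabs, J, K)
  N <- length(state@v)
  eta <- state@v + if (ncol(W)) state@beta %*% t(W) else matrix(0, N, J * K)
  array(invLogit(eta), c(N, J, K))
}

#' Marginal likelihood of one species-site detection history
#'
#' The latent occupancy state is summed out analytically: with at least one
#' detection the history implies presence and the likelihood is
#' \code{psi * prod(p^x * (1-p)^(1-x))}; with none it is
#' \code{psi * prod(1-p) + (1-psi)}. Only occasions selected by the mask
#' contribute; a fully unobserved history has likelihood 1.
#'
#' @param history binary vector of length K.
#' @param psi occupancy probability in (0, 1).
#' @param p detection probabilities, vector of length K in (0, 1).
#' @param mask binary vector of surveyed occasions (default all surveyed).
#' @return the likelihood value.
#' @export
speciesSiteMarginalLik <- function(history, psi, p, mask = NULL) {
  K <- length(history)
  if (is.null(mask)) mask <- rep(1, K)
  if (any(history == 1 & mask == 0)) {
    stop("detection recorded on an unobserved occasion")
  }
  obs <- mask == 1
  if (!any(obs)) return(1)
  x <- history[obs]
  pk <- p[obs]
  if (any(x == 1)) {
    psi * prod(pk^x * (1 - pk)^(1 - x))
  } else {
    psi * prod(1 - pk) + (1 - psi)
  }
}

#' Total log-likelihood of a detection dataset
#'
#' Sum over all species-site cells of the log marginal likelihood, using
#' the survey mask of the data.
#'
#' @param data a \code{DetectionData}.
#' @param psi N x J occupancy probability matrix.
#' @param p N x J x K detection probability array.
#' @return scalar log-likelihood (finite for probabilities in (0, 1)).
#' @export
totalLogLik <- function(data, psi, p) {
  d <- dim(data@x)
  if (!all(dim(psi) == d[1:2]) || !all(dim(p) == d)) {
    stop("dimension mismatch between data and probabilities")
  }
  maskA <- aperm(array(data@mask, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  # per-cell log of: prod over observed k of p^x (1-p)^(1-x)
  logDet <- rowSums(array(maskA * (data@x * log(p) + (1 - data@x) * log1p(-p)),
                          d), dims = 2L)
  logNoDet <- rowSums(array(maskA * log1p(-p), d), dims = 2L)
  anyDet <- rowSums(array(data@x, d), dims = 2L) > 0
  anyObs <- matrix(rep(rowSums(data@mask) > 0, each = d[1L]), d[1L], d[2L])
  ll <- ifelse(anyDet,
               log(psi) + logDet,
               log(psi * exp(logNoDet) + (1 - psi)))
  sum(ll[anyObs])
}

#' Log prior density of a parameter state
#'
#' Species-level effects are Normal(community mean, community sd) within
#' each effect family; non-fixed hyper-means are Normal(0, hyperMeanPriorSD)
#' and non-fixed hyper-sds Uniform(0, hyperSdUpper). A hyper-sd outside the
#' uniform support yields \code{-Inf}.
#'
#' @param state a \code{ParameterState}.
#' @param spec a \code{ModelSpec} (hyper-prior settings and fixed families).
#' @return scalar log density.
#' @export
logPrior <- function(state, spec) {
  tau <- spec@hyperMeanPriorSD
  upper <- spec@hyperSdUpper
  total <- 0
  fam <- function(values, mu, sigma, name) {
    fixed <- name %in% names(spec@fixedHyperMean)
    out <- sum(stats::dnorm(values, mu, sigma, log = TRUE))
    if (!fixed) {
      if (sigma <= 0 || sigma > upper) return(-Inf)
      out <- out + stats::dnorm(mu, 0, tau, log = TRUE) +
        stats::dunif(sigma, 0, upper, log = TRUE)
    }
    out
  }
  total <- total + fam(state@u, state@muU, state@sigmaU, "u")
  total <- total + fam(state@v, state@muV, state@sigmaV, "v")
  for (ci in seq_len(ncol(state@alpha))) {
    nm <- colnames(state@alpha)[ci]
    total <- total + fam(state@alpha[, ci], state@muAlpha[nm],
                         state@sigmaAlpha[nm], paste0("alpha.", nm))
  }
  for (ci in seq_len(ncol(state@beta))) {
    nm <- colnames(state@beta)[ci]
    total <- total + fam(state@beta[, ci], state@muBeta[nm],
                         state@sigmaBeta[nm], paste0("beta.", nm))
  }
  unname(total)
}

#' Full conditional probability that a site is occupied
#'
#' With any detection the species is certainly present. Without one,
#' \code{P(z = 1 | history) = psi * prod(1-p) / (psi * prod(1-p) + 1 - psi)}
#' over the observed occasions.
#'
#' @inheritParams speciesSiteMarginalLik
#' @return probability that the latent occupancy state equals 1.
#' @export
zFullConditional <- function(history, psi, p, mask = NULL) {
  K <- length(history)
  if (is.null(mask)) mask <- rep(1, K)
  obs <- mask == 1
  if (any(history[obs] == 1)) return(1)
  q <- psi * prod(1 - p[obs])
  q / (q + 1 - psi)
}
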