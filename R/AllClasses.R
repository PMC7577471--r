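#' @import methods
NULL

#' Detection/non-detection histories for a species community
#'
#' Binary detection records \code{x[i, j, k]} for species \code{i} at site
#' \code{j} on survey occasion \code{k}, together with a site-by-occasion
#' mask marking which occasions were actually surveyed. Cells outside the
#' mask carry no information and are excluded from all likelihoods and
#' counts.
#'
#' @slot x binary \code{array} of dimension N species x J sites x K occasions.
#' @slot mask binary \code{matrix} J x K; 1 where the occasion was surveyed.
#' @slot species character vector of species labels (length N, unique).
#' @slot sites character vector of site labels (length J, unique).
#' @slot occasions character vector of occasion labels (length K, unique).
#' @export
setClass("DetectionData",
  representation(
    x = "array",
    mask = "matrix",
    species = "character",
    sites = "character",
    occasions = "character"
  )
)

setValidity("DetectionData", function(object) {
  d <- dim(object@x)
  msgs <- character()
  if (length(d) != 3L) {
    return("x must be a 3-d array (species x site x occasion)")
  }
  if (any(d < 1L)) msgs <- c(msgs, "all of N, J, K must be >= 1")
  if (length(object@species) != d[1L]) msgs <- c(msgs, "species labels must match dim 1 of x")
  if (length(object@sites) != d[2L]) msgs <- c(msgs, "site labels must match dim 2 of x")
  if (length(object@occasions) != d[3L]) msgs <- c(msgs, "occasion labels must match dim 3 of x")
  for (lab in list(object@species, object@sites, object@occasions)) {
    if (anyDuplicated(lab)) msgs <- c(msgs, "axis labels must be unique")
  }
  if (!all(dim(object@mask) == d[2:3])) {
    msgs <- c(msgs, "mask must be J x K")
  } else {
    if (!all(object@mask %in% c(0, 1))) msgs <- c(msgs, "mask values must be 0 or 1")
    obs <- aperm(array(object@mask, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
    xs <- object@x[obs == 1]
    if (!all(xs %in% c(0, 1))) msgs <- c(msgs, "x must be 0 or 1 on observed occasions")
    if (any(object@x[obs == 0] != 0)) msgs <- c(msgs, "x must be 0 where mask is 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Named covariates at site or site-by-occasion level
#'
#' Holds a block of numeric covariates at either site level (J x C matrix)
#' or site-by-occasion level (J x K x C array), with standardization
#' metadata so raw values can always be recovered and prediction grids can
#' be placed on the scale of a fit.
#'
#' @slot values numeric matrix (site level, J x C) or array (J x K x C).
#' @slot level \code{"site"} or \code{"site_occasion"}.
#' @slot covariates character vector of covariate names (length C).
#' @slot sites character site labels.
#' @slot occasions character occasion labels (length 0 for site level).
#' @slot standardized logical flag.
#' @slot center,scale named numeric vectors recorded when standardized.
#' @export
setClass("CovariateTable",
  representation(
    values = "ANY",
    level = "character",
    covariates = "character",
    sites = "character",
    occasions = "character",
    standardized = "logical",
    center = "numeric",
    scale = "numeric"
  ),
  prototype(standardized = FALSE, center = numeric(), scale = numeric())
)

setValidity("CovariateTable", function(object) {
  msgs <- character()
  if (!object@level %in% c("site", "site_occasion")) {
    return("level must be 'site' or 'site_occasion'")
  }
  v <- object@values
  if (object@level == "site") {
    if (!is.matrix(v)) return("site-level values must be a J x C matrix")
    if (ncol(v) != length(object@covariates)) msgs <- c(msgs, "covariate names must match columns")
    if (nrow(v) != length(object@sites)) msgs <- c(msgs, "site labels must match rows")
  } else {
    if (!(is.array(v) && length(dim(v)) == 3L)) return("occasion-level values must be a J x K x C array")
    if (dim(v)[3L] != length(object@covariates)) msgs <- c(msgs, "covariate names must match dim 3")
    if (dim(v)[1L] != length(object@sites)) msgs <- c(msgs, "site labels must match dim 1")
    if (dim(v)[2L] != length(object@occasions)) msgs <- c(msgs, "occasion labels must match dim 2")
  }
  if (anyDuplicated(object@covariates)) msgs <- c(msgs, "covariate names must be unique")
  if (object@standardized) {
    # note: a table standardized with ANOTHER table's scaling (e.g. a
    # prediction grid on a fit's scale) need not have sample mean 0 / sd 1,
    # so only the scaling metadata is validated here; standardizeCovariates
    # guarantees the mean-0/sd-1 post-condition for self-standardized tables
    if (!identical(sort(names(object@center)), sort(object@covariates)) ||
        !identical(sort(names(object@scale)), sort(object@covariates))) {
      msgs <- c(msgs, "standardized tables must carry center/scale per covariate")
    } else if (any(object@scale <= 0)) {
      msgs <- c(msgs, "recorded scaling sd must be > 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Model specification for the occupancy and detection submodels
#'
#' Names the covariates that enter each logit-linear submodel and carries
#' the hyper-prior settings for the community-level parameters. Detection
#' covariate sets may differ between datasets; both sets may be empty
#' (intercept-only submodels).
#'
#' @slot occupancyCovariates,detectionCovariates ordered character vectors.
#' @slot hyperMeanPriorSD prior sd of community hyper-means (Normal, mean 0)
#'   on the logit scale; default 2.25.
#' @slot hyperSdUpper upper bound of the Uniform(0, upper) prior on
#'   community hyper-sds; default 5.
#' @slot fixedHyperMean,fixedHyperSd optional named numeric vectors fixing
#'   the hyper-parameters of individual effect families (names like
#'   \code{"u"}, \code{"v"}, \code{"alpha.forest"}, \code{"beta.date"});
#'   fixed families are excluded from hyper-parameter updates.
#' @export
setClass("ModelSpec",
  representation(
    occupancyCovariates = "character",
    detectionCovariates = "character",
    hyperMeanPriorSD = "numeric",
    hyperSdUpper = "numeric",
    fixedHyperMean = "numeric",
    fixedHyperSd = "numeric"
  ),
  prototype(
    hyperMeanPriorSD = 2.25,
    hyperSdUpper = 5,
    fixedHyperMean = numeric(),
    fixedHyperSd = numeric()
  )
)

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (length(object@hyperMeanPriorSD) != 1L || object@hyperMeanPriorSD <= 0) {
    msgs <- c(msgs, "hyperMeanPriorSD must be a positive scalar")
  }
  if (length(object@hyperSdUpper) != 1L || object@hyperSdUpper <= 0) {
    msgs <- c(msgs, "hyperSdUpper must be a positive scalar")
  }
  if (length(object@fixedHyperSd) && any(object@fixedHyperSd <= 0)) {
    msgs <- c(msgs, "fixed hyper-sds must be > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' One state of all latent quantities of the model
#'
#' Species-level intercepts and coefficients, community hyper-parameters
#' and the latent occupancy matrix of a single MCMC state.
#'
#' @slot u,v numeric vectors (length N) of species occupancy / detection
#'   intercepts.
#' @slot alpha,beta numeric matrices N x C of species coefficients for the
#'   occupancy / detection covariates (columns named).
#' @slot muU,muV,sigmaU,sigmaV scalar community hyper-parameters for the
#'   intercept families (sds > 0).
#' @slot muAlpha,muBeta,sigmaAlpha,sigmaBeta named numeric vectors of
#'   hyper-parameters per covariate.
#' @slot z binary N x J latent occupancy matrix.
#' @export
setClass("ParameterState",
  representation(
    u = "numeric", v = "numeric",
    alpha = "matrix", beta = "matrix",
    muU = "numeric", muV = "numeric",
    sigmaU = "numeric", sigmaV = "numeric",
    muAlpha = "numeric", muBeta = "numeric",
    sigmaAlpha = "numeric", sigmaBeta = "numeric",
    z = "matrix"
  )
)

setValidity("ParameterState", function(object) {
  msgs <- character()
  sds <- c(object@sigmaU, object@sigmaV, object@sigmaAlpha, object@sigmaBeta)
  if (any(sds <= 0)) msgs <- c(msgs, "all hyper-sds must be strictly positive")
  if (length(object@z) && !all(object@z %in% c(0, 1))) {
    msgs <- c(msgs, "z must be binary")
  }
  if (length(msgs)) msgs else TRUE
})

#' MCMC run configuration
#'
#' @slot chains number of independent chains (default 3).
#' @slot iterations total iterations per chain (default 150000).
#' @slot burnin discarded initial iterations (default 50000).
#' @slot thin retention stride after burn-in (default 100).
#' @slot baseSeed integer seed; per-chain seeds are derived from it.
#' @slot adaptUntil iteration after which proposal adaptation is frozen;
#'   defaults to the burn-in end so retained draws keep detailed balance.
#' @slot storeZ logical; store thinned latent occupancy draws (needed for
#'   \code{\link{estimatedRichness}}).
#' @export
setClass("McmcConfig",
  representation(
    chains = "integer", iterations = "integer", burnin = "integer",
    thin = "integer", baseSeed = "integer", adaptUntil = "integer",
    storeZ = "logical"
  ),
  prototype(
    chains = 3L, iterations = 150000L, burnin = 50000L, thin = 100L,
    baseSeed = 1L, adaptUntil = NA_integer_, storeZ = TRUE
  )
)

setValidity("McmcConfig", function(object) {
  msgs <- character()
  if (object@burnin >= object@iterations) msgs <- c(msgs, "burnin must be < iterations")
  if (object@thin < 1L) msgs <- c(msgs, "thin must be >= 1")
  if (object@chains < 1L) msgs <- c(msgs, "need at least one chain")
  if (length(msgs)) msgs else TRUE
})

#' Retained posterior draws with provenance
#'
#' Draws are stored per chain as a numeric matrix (retained draws x named
#' parameters); optional thinned latent-occupancy draws support
#' detection-corrected richness. The object carries the configuration,
#' model specification, covariate scaling and acceptance rates needed to
#' reconstruct or extend the fit.
#'
#' @slot draws list of per-chain matrices with identical column names.
#' @slot zDraws list (per chain) of N x J x draws arrays, or empty list.
#' @slot config the \code{McmcConfig} used.
#' @slot modelSpec the \code{ModelSpec} used.
#' @slot species,sites character labels carried from the data.
#' @slot scaling list of per-table center/scale used to standardize the
#'   covariates of the fit (for placing prediction grids on the same scale).
#' @slot acceptance named numeric vector of post-burn-in acceptance rates
#'   per adapted proposal family.
#' @export
setClass("PosteriorSamples",
  representation(
    draws = "list",
    zDraws = "list",
    config = "McmcConfig",
    modelSpec = "ModelSpec",
    species = "character",
    sites = "character",
    scaling = "list",
    acceptance = "numeric"
  )
)

setValidity("PosteriorSamples", function(object) {
  msgs <- character()
  if (!length(object@draws)) return("no chains stored")
  cn <- colnames(object@draws[[1L]])
  per <- retainedPerChain(object@config)
  for (m in object@draws) {
    if (!identical(colnames(m), cn)) msgs <- c(msgs, "chains must share parameter names")
    if (nrow(m) != per) msgs <- c(msgs, "retained draw count must match the config formula")
  }
  if (length(object@zDraws) && length(object@zDraws) != length(object@draws)) {
    msgs <- c(msgs, "zDraws must have one entry per chain")
  }
  if (length(msgs)) unique(msgs) else TRUE
})

#' Posterior-predictive goodness-of-fit result
#'
#' @slot bayesP Bayesian p-value: fraction of retained draws whose observed
#'   chi-square discrepancy exceeds the replicated one; values outside
#'   (0.05, 0.95) indicate lack of fit.
#' @slot chi2Obs,chi2Sim per-draw discrepancies for observed and replicated
#'   data.
#' @export
setClass("GofResult",
  representation(bayesP = "numeric", chi2Obs = "numeric", chi2Sim = "numeric")
)

setValidity("GofResult", function(object) {
  ok <- length(object@chi2Obs) == length(object@chi2Sim) &&
    length(object@bayesP) == 1L && object@bayesP >= 0 && object@bayesP <= 1 &&
    isTRUE(all.equal(object@bayesP, mean(object@chi2Obs > object@chi2Sim)))
  if (ok) TRUE else "bayesP must equal mean(chi2Obs > chi2Sim) in [0, 1]"
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "DetectionData", function(object) {
  d <- dim(object@x)
  cat(sprintf(
    "DetectionData: %d species x %d sites x %d occasions\n", d[1L], d[2L], d[3L]
  ))
  cat(sprintf(
    "  surveyed occasions: %d of %d; total detections: %d\n",
    sum(object@mask), length(object@mask), sum(detectionCounts(object)$detections)
  ))
})

setMethod("show", "CovariateTable", function(object) {
  cat(sprintf(
    "CovariateTable (%s level): %d covariate(s) over %d site(s)%s\n",
    object@level, length(object@covariates), length(object@sites),
    if (object@level == "site_occasion") {
      sprintf(" x %d occasion(s)", length(object@occasions))
    } else ""
  ))
  cat("  ", paste(object@covariates, collapse = ", "), "\n", sep = "")
  cat(sprintf("  standardized: %s\n", object@standardized))
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec\n")
  cat("  occupancy covariates:",
      if (length(object@occupancyCovariates)) paste(object@occupancyCovariates, collapse = ", ") else "(intercept only)", "\n")
  cat("  detection covariates:",
      if (length(object@detectionCovariates)) paste(object@detectionCovariates, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  hyper-priors: mean ~ N(0, %.3g), sd ~ U(0, %.3g)\n",
              object@hyperMeanPriorSD, object@hyperSdUpper))
})

setMethod("show", "McmcConfig", function(object) {
  cat(sprintf(
    "McmcConfig: %d chain(s) x %d iterations (burn-in %d, thin %d) -> %d retained draws\n",
    object@chains, object@iterations, object@burnin, object@thin,
    object@chains * retainedPerChain(object)
  ))
})

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf(
    "PosteriorSamples: %d chain(s) x %d draws of %d parameters (%d species, %d sites)\n",
    length(object@draws), nrow(object@draws[[1L]]), ncol(object@draws[[1L]]),
    length(object@species), length(object@sites)
  ))
  if (length(object@zDraws)) cat("  latent occupancy draws stored\n")
})

setMethod("show", "GofResult", function(object) {
  cat(sprintf(
    "GofResult: Bayesian p-value %.3f over %d draws (%s)\n",
    object@bayesP, length(object@chi2Obs),
    if (object@bayesP > 0.05 && object@bayesP < 0.95) "adequate fit" else "lack of fit"
  ))
})
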