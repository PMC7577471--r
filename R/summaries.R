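# Posterior summarization: parameter tables, effect-strength classes,
# detection-corrected richness and effect tallies.

#' Summarize posterior draws
#'
#' Pooled-chain posterior mean and equal-tailed 95% credible bounds
#' (2.5 and 97.5 linear-interpolation percentiles) per parameter.
#'
#' @param samples a \code{PosteriorSamples} with at least 100 pooled draws.
#' @param parameters character vector of parameter names (default: all).
#' @param ciLevel credible level (default 0.95).
#' @return data.frame with columns \code{parameter, mean, ciLow, ciHigh,
#'   degenerate} (degenerate flags constant draws, whose interval collapses
#'   to a point).
#' @export
summarizePosterior <- function(samples, parameters = NULL, ciLevel = 0.95) {
  pooled <- posteriorDraws(samples, parameters = parameters)
  if (nrow(pooled) < 100L) stop("need at least 100 pooled draws to summarize")
  a <- (1 - ciLevel) / 2
  qs <- apply(pooled, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE,
              type = 7)
  data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    ciLow = qs[1L, ],
    ciHigh = qs[2L, ],
    degenerate = qs[1L, ] == qs[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Classify the strength of a covariate effect
#'
#' Effects are graded from the posterior draws of one coefficient:
#' \emph{strong} if the 95% credible interval excludes zero; otherwise the
#' posterior mass on the dominant side of zero decides between
#' \emph{moderate} (mass >= \code{moderateMass}, i.e. the interval contains
#' zero but is not centered on it) and \emph{weak} (roughly centered on
#' zero). The sign comes from the posterior mean.
#'
#' @param draws numeric vector of >= 100 posterior draws of one coefficient.
#' @param ciLevel credible level for the strong test (default 0.95).
#' @param moderateMass one-sided mass threshold separating moderate from
#'   weak (default 0.80).
#' @return an \code{EffectClass}: list with \code{label} (strong, moderate
#'   or weak), \code{sign} (positive/negative), \code{sideMass}, and the
#'   credible bounds.
#' @export
classifyEffect <- function(draws, ciLevel = 0.95, moderateMass = 0.80) {
  if (length(draws) < 100L) stop("need at least 100 draws to classify an effect")
  a <- (1 - ciLevel) / 2
  ci <- stats::quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
  sideMass <- max(mean(draws > 0), mean(draws < 0))
  label <- if (ci[1L] > 0 || ci[2L] < 0) {
    "strong"
  } else if (sideMass >= moderateMass) {
    "moderate"
  } else {
    "weak"
  }
  structure(
    list(label = label,
         sign = if (mean(draws) >= 0) "positive" else "negative",
         sideMass = sideMass, ciLow = ci[1L], ciHigh = ci[2L]),
    class = "EffectClass"
  )
}

#' @export
print.EffectClass <- function(x, ...) {
  cat(sprintf("EffectClass: %s %s (side mass %.3f, 95%% CI %.3f to %.3f)\n",
              x$label, x$sign, x$sideMass, x$ciLow, x$ciHigh))
  invisible(x)
}

#' Per-species effect classes for one covariate
#'
#' @param samples a \code{PosteriorSamples}.
#' @param covariate covariate name.
#' @param submodel \code{"occupancy"} (alpha coefficients) or
#'   \code{"detection"} (beta coefficients).
#' @param ... passed to \code{\link{classifyEffect}}.
#' @return data.frame with one row per species: label, sign, sideMass and
#'   credible bounds.
#' @export
speciesEffectTable <- function(samples, covariate,
                               submodel = c("occupancy", "detection"), ...) {
  submodel <- match.arg(submodel)
  stub <- if (submodel == "occupancy") "alpha." else "beta."
  N <- length(samples@species)
  pars <- paste0(stub, covariate, "[", seq_len(N), "]")
  pooled <- posteriorDraws(samples, parameters = pars)
  rows <- lapply(seq_len(N), function(i) {
    cl <- classifyEffect(pooled[, i], ...)
    data.frame(species = samples@species[i], covariate = covariate,
               label = cl$label, sign = cl$sign, sideMass = cl$sideMass,
               ciLow = cl$ciLow, ciHigh = cl$ciHigh,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tally effect classes across species
#'
#' Counts species in each strength-by-sign cell and reports the percentage
#' of species with a negative posterior-mean effect, as used when
#' summarizing how many community members respond to a covariate.
#'
#' @param classes a data.frame with columns \code{label} and \code{sign}
#'   (one row per species), e.g. from \code{\link{speciesEffectTable}}.
#' @return list with \code{counts} (3 x 2 table strong/moderate/weak by
#'   positive/negative), \code{n}, \code{pctNegative} and per-label
#'   percentages.
#' @export
effectTally <- function(classes) {
  labels <- c("strong", "moderate", "weak")
  signs <- c("positive", "negative")
  counts <- matrix(0L, 3L, 2L, dimnames = list(labels, signs))
  if (nrow(classes)) {
    tab <- table(factor(classes$label, labels), factor(classes$sign, signs))
    counts[] <- as.integer(tab)
  }
  n <- nrow(classes)
  list(
    counts = counts,
    n = n,
    pctNegative = if (n) 100 * sum(classes$sign == "negative") / n else 0,
    pctStrong = if (n) 100 * sum(classes$label == "strong") / n else 0
  )
}

#' Detection-corrected species richness per site or group
#'
#' Richness per retained draw is the number of species whose latent
#' occupancy state is 1 at the site (or at any site of the group); the
#' posterior mean and equal-tailed 95% interval are taken over draws.
#' Because the latent state is forced to 1 wherever a species was detected,
#' estimated richness is bounded below by observed richness at every site
#' and draw.
#'
#' @param samples a \code{PosteriorSamples} fitted with \code{storeZ = TRUE}.
#' @param data the fitted \code{DetectionData} (for observed richness).
#' @param grouping optional named character vector mapping sites to groups
#'   (e.g. habitat classes); default: per site.
#' @return data.frame with columns \code{group, observed, mean, ciLow,
#'   ciHigh}.
#' @export
estimatedRichness <- function(samples, data, grouping = NULL) {
  if (!length(samples@zDraws)) {
    stop("no latent-occupancy draws stored: re-run the fit with storeZ = TRUE")
  }
  z <- do.call(abind3, samples@zDraws)           # N x J x R
  R <- dim(z)[3L]
  obs <- observedRichness(data, grouping)
  if (is.null(grouping)) {
    rich <- apply(z, 3L, colSums)                 # J x R
    groups <- samples@sites
  } else {
    groups <- names(obs)
    siteGroup <- grouping[samples@sites]
    rich <- vapply(groups, function(g) {
      js <- which(siteGroup == g)
      apply(z[, js, , drop = FALSE], 3L, function(m) sum(rowSums(m) > 0))
    }, numeric(R))
    rich <- t(rich)                               # groups x R
  }
  qs <- apply(rich, 1L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 7)
  data.frame(
    group = groups,
    observed = as.integer(obs[groups]),
    mean = rowMeans(rich),
    ciLow = qs[1L, ],
    ciHigh = qs[2L, ],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Expected species richness over a covariate grid
#'
#' For each grid row the expected richness is the posterior mean of
#' \code{sum_i psi_i(x)}: the sum over species of occupancy probabilities
#' at the grid covariates. This is the smooth, detection-corrected richness
#' surface; it is bounded by [0, N].
#'
#' @param samples a \code{PosteriorSamples}.
#' @param grid site-level \code{CovariateTable} of grid rows holding
#'   exactly the occupancy covariates of the fit, standardized with the
#'   fit's scaling (see \code{\link{applyScaling}} and
#'   \code{scalingInfo(samples)$site}).
#' @param ci report equal-tailed 95% bounds over draws (default TRUE).
#' @return data.frame with columns \code{row, richness} and optionally
#'   \code{ciLow, ciHigh}.
#' @export
predictRichness <- function(samples, grid, ci = TRUE) {
  spec <- samples@modelSpec
  if (!setequal(grid@covariates, spec@occupancyCovariates)) {
    stop("grid covariates must match the fit's occupancy covariates: ",
         paste(spec@occupancyCovariates, collapse = ", "))
  }
  if (length(spec@occupancyCovariates) && !grid@standardized) {
    stop("standardize the grid with the fit's scaling first (applyScaling)")
  }
  X <- occupancyDesign(spec@occupancyCovariates, grid)
  G <- nrow(X)
  N <- length(samples@species)
  pooled <- posteriorDraws(samples)
  cn <- colnames(pooled)
  uIdx <- match(paste0("u[", seq_len(N), "]"), cn)
  aIdx <- lapply(spec@occupancyCovariates, function(nm)
    match(paste0("alpha.", nm, "[", seq_len(N), "]"), cn))
  R <- nrow(pooled)
  rich <- matrix(NA_real_, G, R)
  for (r in seq_len(R)) {
    row <- pooled[r, ]
    eta <- row[uIdx] + if (length(aIdx)) {
      vapply(aIdx, function(ix) row[ix], numeric(N)) %*% t(X)
    } else {
      matrix(0, N, G)
    }
    rich[, r] <- colSums(invLogit(matrix(eta, N, G)))
  }
  out <- data.frame(row = grid@sites, richness = rowMeans(rich),
                    stringsAsFactors = FALSE)
  if (ci) {
    qs <- apply(rich, 1L, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE, type = 7)
    out$ciLow <- qs[1L, ]
    out$ciHigh <- qs[2L, ]
  }
  out
}
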