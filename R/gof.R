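# Posterior-predictive goodness-of-fit: Bayesian p-value on a chi-square
# discrepancy over species-by-site detection totals.

#' Bayesian p-value for posterior-predictive fit
#'
#' For every retained draw, expected detection totals per species-site cell
#' are computed as \code{E = psi * sum_k p} over surveyed occasions
#' (marginal over the latent state; set \code{conditionOnZ = TRUE} to use
#' the sampled latent state instead) and compared with the observed totals
#' through a stabilized Pearson discrepancy
#' \code{chi2 = sum (O - E)^2 / (E + 0.5)}. A replicate dataset is then
#' simulated from the model at the same draw and its discrepancy computed
#' identically. The Bayesian p-value is the fraction of draws whose
#' observed discrepancy exceeds the replicated one; values outside
#' (0.05, 0.95) indicate lack of fit.
#'
#' @param samples a \code{PosteriorSamples}.
#' @param data the \code{DetectionData} that was fitted.
#' @param siteCovariates,occasionCovariates the standardized covariate
#'   tables of the fit.
#' @param conditionOnZ use the stored latent-occupancy draws instead of
#'   marginal occupancy probabilities (requires stored z draws).
#' @param seed integer seed for the replicate simulations.
#' @return a \code{\linkS4class{GofResult}}.
#' @export
bayesianPValue <- function(samples, data, siteCovariates = NULL,
                           occasionCovariates = NULL, conditionOnZ = FALSE,
                           seed = 1L) {
  spec <- samples@modelSpec
  d <- dim(data@x)
  N <- d[1L]; J <- d[2L]; K <- d[3L]; M <- J * K
  X <- if (is.null(siteCovariates)) matrix(0, J, 0L) else
    occupancyDesign(spec@occupancyCovariates, siteCovariates)
  W <- detectionDesign(spec@detectionCovariates,
                       list(occasionCovariates, siteCovariates), J, K)
  xm <- matrix(data@x, N, M)
  maskM <- matrix(rep(as.numeric(data@mask), each = N), N, M)
  sidx <- rep(seq_len(J), K)
  O <- rowSums(array(maskM * xm, c(N, J, K)), dims = 2L)   # N x J observed totals

  pooled <- posteriorDraws(samples)
  cn <- colnames(pooled)
  uIdx <- match(paste0("u[", seq_len(N), "]"), cn)
  vIdx <- match(paste0("v[", seq_len(N), "]"), cn)
  aIdx <- lapply(spec@occupancyCovariates, function(nm)
    match(paste0("alpha.", nm, "[", seq_len(N), "]"), cn))
  bIdx <- lapply(spec@detectionCovariates, function(nm)
    match(paste0("beta.", nm, "[", seq_len(N), "]"), cn))

  zPooled <- NULL
  if (conditionOnZ) {
    if (!length(samples@zDraws)) {
      stop("conditionOnZ requires stored latent-occupancy draws")
    }
    zPooled <- do.call(abind3, samples@zDraws)
  }

  set.seed(as.integer(seed))
  R <- nrow(pooled)
  chi2Obs <- numeric(R)
  chi2Sim <- numeric(R)
  for (r in seq_len(R)) {
    row <- pooled[r, ]
    alpha <- vapply(aIdx, function(ix) row[ix], numeric(N))
    beta <- vapply(bIdx, function(ix) row[ix], numeric(N))
    etaPsi <- row[uIdx] + if (length(aIdx)) matrix(alpha, N) %*% t(X) else 0
    psi <- invLogit(matrix(etaPsi, N, J))
    etaP <- row[vIdx] + if (length(bIdx)) matrix(beta, N) %*% t(W) else 0
    p <- matrix(invLogit(matrix(etaP, N, M)), N, M)
    sumP <- rowSums(array(maskM * p, c(N, J, K)), dims = 2L)  # N x J
    E <- if (conditionOnZ) zPooled[, , r] * sumP else psi * sumP
    chi2Obs[r] <- sum((O - E)^2 / (E + 0.5))
    # replicate dataset from the model at this draw
    zRep <- matrix(stats::runif(N * J), N, J) < psi
    xRep <- (matrix(stats::runif(N * M), N, M) < p * zRep[, sidx]) * maskM
    ORep <- rowSums(array(xRep, c(N, J, K)), dims = 2L)
    chi2Sim[r] <- sum((ORep - E)^2 / (E + 0.5))
  }
  new("GofResult", bayesP = mean(chi2Obs > chi2Sim),
      chi2Obs = chi2Obs, chi2Sim = chi2Sim)
}

# bind N x J x R arrays along the third dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  array(do.call(c, lapply(arrs, as.vector)),
        c(d[1L], d[2L], sum(vapply(arrs, function(a) dim(a)[3L], numeric(1)))))
}
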