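# Convergence diagnostics and Monte-Carlo error.

#' Split-chain rank-normalized Gelman-Rubin diagnostic
#'
#' Each chain is split in half, pooled draws are rank-normalized
#' (normal scores of average ranks), and the classic potential scale
#' reduction factor is computed over the split chains. This variant is
#' more conservative than the unsplit, unnormalized statistic. Values
#' near 1 indicate convergence; the usual threshold is 1.1.
#'
#' @param samples a \code{PosteriorSamples} with at least 2 chains and at
#'   least 4 retained draws per chain, or a list of per-chain numeric
#'   matrices with identical column names.
#' @param parameters optional subset of parameter names.
#' @return named numeric vector of R-hat values (constant parameters get
#'   \code{NA}).
#' @export
gelmanRubin <- function(samples, parameters = NULL) {
  mats <- if (methods::is(samples, "PosteriorSamples")) {
    posteriorDraws(samples, parameters = parameters, pool = FALSE)
  } else {
    samples
  }
  if (length(mats) < 2L) stop("R-hat needs at least 2 chains")
  n <- nrow(mats[[1L]])
  if (n < 4L) stop("R-hat needs at least 4 retained draws per chain")
  cn <- colnames(mats[[1L]])
  out <- stats::setNames(rep(NA_real_, length(cn)), cn)
  half <- n %/% 2L
  for (pi in seq_along(cn)) {
    chains <- lapply(mats, function(m) m[, pi])
    splits <- unlist(lapply(chains, function(x) {
      x <- x[(n - 2L * half + 1L):n]          # drop a leading draw if n is odd
      list(x[seq_len(half)], x[half + seq_len(half)])
    }), recursive = FALSE)
    pooled <- unlist(splits)
    if (stats::var(pooled) == 0) next
    S <- length(pooled)
    zn <- stats::qnorm((rank(pooled, ties.method = "average") - 3 / 8) / (S + 1 / 4))
    zs <- split(zn, rep(seq_along(splits), each = half))
    means <- vapply(zs, mean, numeric(1))
    vars <- vapply(zs, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    varPlus <- (half - 1) / half * W + B / half
    out[pi] <- sqrt(varPlus / W)
  }
  out
}

#' Maximum R-hat over all parameters of a fit
#'
#' @param samples a \code{PosteriorSamples}.
#' @return scalar max R-hat (ignoring constant parameters).
#' @export
maxRhat <- function(samples) {
  r <- gelmanRubin(samples)
  if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
}

#' Monte-Carlo standard error by batch means
#'
#' Splits a draw sequence into roughly sqrt(n) consecutive batches and
#' estimates the standard error of the sample mean from the batch means,
#' which absorbs autocorrelation.
#'
#' @param x numeric vector of (possibly autocorrelated) draws.
#' @return scalar Monte-Carlo standard error of \code{mean(x)}.
#' @export
mcmcStandardError <- function(x) {
  n <- length(x)
  b <- max(2L, floor(sqrt(n)))
  nb <- n %/% b
  if (nb < 2L) return(stats::sd(x) / sqrt(n))
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1L) * b + 1L):(i * b)]),
               numeric(1))
  stats::sd(bm) / sqrt(nb)
}
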