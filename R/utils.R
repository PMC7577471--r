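# Numerical helpers shared across the package.

# Linear predictors are clipped to +/- ETA_CLIP before the inverse logit so
# probabilities stay strictly inside (0, 1) in double precision.
ETA_CLIP <- 35

#' @noRd
clipEta <- function(eta) pmin(pmax(eta, -ETA_CLIP), ETA_CLIP)

#' Inverse logit with guarded linear predictor
#'
#' Maps a logit-scale linear predictor to a probability strictly inside
#' (0, 1); inputs beyond +/-35 saturate at `plogis(35)` rather than at exact
#' 0 or 1.
#'
#' @param eta numeric vector, matrix or array of linear predictors.
#' @return object of the same shape with values in the open unit interval.
#' @export
invLogit <- function(eta) stats::plogis(clipEta(eta))

# log(1 + exp(x)), numerically stable for large |x|.
log1pexp <- function(x) {
  out <- x
  small <- x < 33
  out[small] <- log1p(exp(x[small]))
  out
}

# Bernoulli log-likelihood on the logit scale: y*eta - log(1 + exp(eta)).
bernLoglikLogit <- function(y, eta) {
  eta <- clipEta(eta)
  y * eta - log1pexp(eta)
}

# Deterministic 32-bit sub-seed derivation: base seed plus a stream offset,
# folded into [0, 2^31).
deriveSeed <- function(base, stream) {
  as.integer((as.numeric(base) * 1000 + as.numeric(stream)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
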