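# Accessor generics: user code reads slots through these, never with @.

#' @rdname accessors
#' @export
setGeneric("speciesIds", function(object) standardGeneric("speciesIds"))
#' @rdname accessors
#' @export
setGeneric("siteIds", function(object) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setGeneric("occasionIds", function(object) standardGeneric("occasionIds"))
#' @rdname accessors
#' @export
setGeneric("detectionArray", function(object) standardGeneric("detectionArray"))
#' @rdname accessors
#' @export
setGeneric("observedMask", function(object) standardGeneric("observedMask"))
#' @rdname accessors
#' @export
setGeneric("covariateNames", function(object) standardGeneric("covariateNames"))
#' @rdname accessors
#' @export
setGeneric("covariateValues", function(object) standardGeneric("covariateValues"))
#' @rdname accessors
#' @export
setGeneric("isStandardized", function(object) standardGeneric("isStandardized"))
#' @rdname accessors
#' @export
setGeneric("scalingInfo", function(object) standardGeneric("scalingInfo"))
#' @rdname accessors
#' @export
setGeneric("posteriorDraws", function(object, ...) standardGeneric("posteriorDraws"))
#' @rdname accessors
#' @export
setGeneric("latentOccupancyDraws", function(object) standardGeneric("latentOccupancyDraws"))
#' @rdname accessors
#' @export
setGeneric("mcmcConfig", function(object) standardGeneric("mcmcConfig"))
#' @rdname accessors
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))
#' @rdname accessors
#' @export
setGeneric("acceptanceRates", function(object) standardGeneric("acceptanceRates"))
#' @rdname accessors
#' @export
setGeneric("bayesP", function(object) standardGeneric("bayesP"))

#' Accessors for msoccu containers
#'
#' Small read-only accessors for the S4 containers: axis labels, the
#' detection array and survey mask, covariate values and standardization
#' metadata, and the components of a posterior fit.
#'
#' @param object an msoccu S4 object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("speciesIds", "DetectionData", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("siteIds", "DetectionData", function(object) object@sites)
#' @rdname accessors
#' @export
setMethod("occasionIds", "DetectionData", function(object) object@occasions)
#' @rdname accessors
#' @export
setMethod("detectionArray", "DetectionData", function(object) object@x)
#' @rdname accessors
#' @export
setMethod("observedMask", "DetectionData", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("siteIds", "CovariateTable", function(object) object@sites)
#' @rdname accessors
#' @export
setMethod("occasionIds", "CovariateTable", function(object) object@occasions)
#' @rdname accessors
#' @export
setMethod("covariateNames", "CovariateTable", function(object) object@covariates)
#' @rdname accessors
#' @export
setMethod("covariateValues", "CovariateTable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("isStandardized", "CovariateTable", function(object) object@standardized)
#' @rdname accessors
#' @export
setMethod("scalingInfo", "CovariateTable", function(object) {
  list(center = object@center, scale = object@scale)
})

#' @rdname accessors
#' @export
setMethod("speciesIds", "PosteriorSamples", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("siteIds", "PosteriorSamples", function(object) object@sites)
#' @rdname accessors
#' @export
setMethod("mcmcConfig", "PosteriorSamples", function(object) object@config)
#' @rdname accessors
#' @export
setMethod("modelSpec", "PosteriorSamples", function(object) object@modelSpec)
#' @rdname accessors
#' @export
setMethod("acceptanceRates", "PosteriorSamples", function(object) object@acceptance)
#' @rdname accessors
#' @export
setMethod("scalingInfo", "PosteriorSamples", function(object) object@scaling)
#' @rdname accessors
#' @export
setMethod("latentOccupancyDraws", "PosteriorSamples", function(object) object@zDraws)

#' @rdname accessors
#' @param parameters optional character vector restricting to named columns.
#' @param pool if \code{TRUE} (default) chains are row-bound into one matrix.
#' @export
setMethod("posteriorDraws", "PosteriorSamples", function(object,
                                                         parameters = NULL,
                                                         pool = TRUE) {
  mats <- object@draws
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, colnames(mats[[1L]]))
    if (length(missing)) {
      stop("unknown parameter name(s): ", paste(missing, collapse = ", "))
    }
    mats <- lapply(mats, function(m) m[, parameters, drop = FALSE])
  }
  if (pool) do.call(rbind, mats) else mats
})

#' @rdname accessors
#' @export
setMethod("bayesP", "GofResult", function(object) object@bayesP)

#' Retained draws per chain implied by an MCMC configuration
#'
#' @param config a \code{McmcConfig}.
#' @return integer count \code{(iterations - burnin) / thin}.
#' @export
retainedPerChain <- function(config) {
  as.integer(floor((config@iterations - config@burnin) / config@thin))
}

#' Extract one covariate as a vector or matrix
#'
#' @param table a \code{CovariateTable}.
#' @param name covariate name.
#' @return numeric vector (site level, length J) or J x K matrix.
#' @export
covariateColumn <- function(table, name) {
  idx <- match(name, table@covariates)
  if (is.na(idx)) stop("no covariate named '", name, "'")
  if (table@level == "site") table@values[, idx] else table@values[, , idx]
}
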