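# Plain-text persistence of posterior fits: one delimited table per chain
# plus a JSON manifest; the loader restores draws bit-exactly (values are
# written with 17 significant digits, which round-trips doubles).

#' Write a posterior fit to a directory
#'
#' @param samples a \code{PosteriorSamples}.
#' @param dir output directory (created if absent).
#' @return invisibly, the directory path.
#' @export
writePosteriorSamples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(m) {
    df <- as.data.frame(apply(m, 2L, function(col) sprintf("%.17g", col)),
                        stringsAsFactors = FALSE)
    names(df) <- colnames(m)
    df
  }
  for (ch in seq_along(samples@draws)) {
    utils::write.csv(fmt(samples@draws[[ch]]),
                     file.path(dir, sprintf("chain%d.csv", ch)),
                     row.names = FALSE, quote = FALSE)
  }
  if (length(samples@zDraws)) {
    for (ch in seq_along(samples@zDraws)) {
      z <- samples@zDraws[[ch]]
      m <- matrix(as.integer(z), dim(z)[3L], byrow = TRUE)
      utils::write.csv(as.data.frame(m),
                       file.path(dir, sprintf("z_chain%d.csv", ch)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  cfg <- samples@config
  spec <- samples@modelSpec
  manifest <- list(
    chains = length(samples@draws),
    parameters = colnames(samples@draws[[1L]]),
    species = samples@species,
    sites = samples@sites,
    config = list(
      chains = cfg@chains, iterations = cfg@iterations, burnin = cfg@burnin,
      thin = cfg@thin, baseSeed = cfg@baseSeed, adaptUntil = cfg@adaptUntil,
      storeZ = cfg@storeZ
    ),
    modelSpec = list(
      occupancyCovariates = spec@occupancyCovariates,
      detectionCovariates = spec@detectionCovariates,
      hyperMeanPriorSD = spec@hyperMeanPriorSD,
      hyperSdUpper = spec@hyperSdUpper,
      fixedHyperMean = as.list(spec@fixedHyperMean),
      fixedHyperSd = as.list(spec@fixedHyperSd)
    ),
    scaling = lapply(samples@scaling, function(s)
      list(center = as.list(s$center), scale = as.list(s$scale))),
    acceptance = as.list(samples@acceptance),
    hasZ = length(samples@zDraws) > 0
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a posterior fit written by \code{\link{writePosteriorSamples}}
#'
#' @param dir directory containing chain tables and manifest.
#' @return a \code{PosteriorSamples} equal to the one written.
#' @export
readPosteriorSamples <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  nCh <- man$chains
  draws <- lapply(seq_len(nCh), function(ch) {
    df <- utils::read.csv(file.path(dir, sprintf("chain%d.csv", ch)),
                          check.names = FALSE)
    as.matrix(df)
  })
  species <- man$species
  sites <- man$sites
  zDraws <- list()
  if (isTRUE(man$hasZ)) {
    N <- length(species); J <- length(sites)
    zDraws <- lapply(seq_len(nCh), function(ch) {
      m <- as.matrix(utils::read.csv(file.path(dir, sprintf("z_chain%d.csv", ch))))
      array(as.numeric(t(m)), c(N, J, nrow(m)))
    })
  }
  cfg <- man$config
  ms <- man$modelSpec
  scaling <- lapply(man$scaling, function(s) {
    list(center = unlist(s$center), scale = unlist(s$scale))
  })
  new("PosteriorSamples",
    draws = draws, zDraws = zDraws,
    config = McmcConfig(cfg$chains, cfg$iterations, cfg$burnin, cfg$thin,
                        cfg$baseSeed, cfg$adaptUntil, cfg$storeZ),
    modelSpec = ModelSpec(
      occupancyCovariates = ms$occupancyCovariates %||% character(),
      detectionCovariates = ms$detectionCovariates %||% character(),
      hyperMeanPriorSD = ms$hyperMeanPriorSD,
      hyperSdUpper = ms$hyperSdUpper,
      fixedHyperMean = unlist(ms$fixedHyperMean) %||% numeric(),
      fixedHyperSd = unlist(ms$fixedHyperSd) %||% numeric()
    ),
    species = species, sites = sites,
    scaling = scaling,
    acceptance = unlist(man$acceptance) %||% numeric()
  )
}
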