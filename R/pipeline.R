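# Orchestrated pipeline: config -> data -> covariate preparation -> MCMC ->
# diagnostics, goodness-of-fit and summary tables, with a reproducible run
# manifest. Status codes: 0 success (possibly with a non-convergence
# warning), 2 missing input file, 3 configuration/validation failure.

inputError <- function(msg) {
  stop(errorCondition(msg, class = c("msoccuInputError", "error", "condition")))
}
configError <- function(msg) {
  stop(errorCondition(msg, class = c("msoccuConfigError", "error", "condition")))
}

#' Run the full analysis pipeline from a config file
#'
#' Reads a YAML configuration naming the input tables, model covariates and
#' MCMC settings; standardizes (and optionally screens) the covariates;
#' fits the model; computes convergence diagnostics and the Bayesian
#' p-value; and writes summary tables, the posterior and a run manifest to
#' the output directory. Identical configurations and seeds produce
#' byte-identical outputs.
#'
#' Config schema (YAML):
#' \preformatted{
#' seed: 1
#' out_dir: results
#' data:
#'   detections: detections.csv        # species,site,occasion,detected
#'   manifest: manifest.csv            # site,occasion
#'   site_covariates: site_covs.csv
#'   occasion_covariates: occ_covs.csv # optional
#' model:
#'   occupancy_covariates: [elevation, forest, anthropogenic]
#'   detection_covariates: [date, time]
#' mcmc: {chains: 3, iterations: 150000, burnin: 50000, thin: 100}
#' screen_collinearity: false
#' rhat_threshold: 1.1
#' }
#'
#' @param configPath path to the YAML config.
#' @param outDir overrides \code{out_dir} from the config.
#' @param quiet suppress progress messages.
#' @return list with \code{status} (0/2/3), \code{message}, and on success
#'   \code{manifest}, \code{outputs} (named file paths) and \code{samples}.
#' @export
runPipeline <- function(configPath, outDir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  result <- tryCatch({
    if (!file.exists(configPath)) inputError(paste("config file not found:", configPath))
    cfg <- yaml::read_yaml(configPath)
    seed <- as.integer(cfg$seed %||% 1L)
    outDir <- outDir %||% cfg$out_dir %||% configError("no out_dir configured")
    dataCfg <- cfg$data %||% configError("config lacks a 'data' section")
    paths <- c(
      detections = dataCfg$detections %||% configError("data.detections missing"),
      manifest = dataCfg$manifest %||% NA,
      site_covariates = dataCfg$site_covariates %||% NA,
      occasion_covariates = dataCfg$occasion_covariates %||% NA
    )
    base <- dirname(normalizePath(configPath))
    resolve <- function(p) {
      if (is.na(p)) return(NA_character_)
      if (file.exists(p)) p else file.path(base, p)
    }
    paths <- vapply(paths, resolve, character(1))
    for (nm in names(paths)) {
      if (!is.na(paths[nm]) && !file.exists(paths[nm])) {
        inputError(paste0("missing input file (", nm, "): ", paths[nm]))
      }
    }

    say("reading detection records")
    data <- readDetectionRecords(paths["detections"],
                                 if (!is.na(paths["manifest"])) paths["manifest"])
    siteCovs <- if (!is.na(paths["site_covariates"])) {
      readCovariateTable(paths["site_covariates"], "site")
    }
    occCovs <- if (!is.na(paths["occasion_covariates"])) {
      readCovariateTable(paths["occasion_covariates"], "site_occasion")
    }

    modelCfg <- cfg$model %||% list()
    occNames <- as.character(modelCfg$occupancy_covariates %||% character())
    detNames <- as.character(modelCfg$detection_covariates %||% character())
    available <- c(if (!is.null(siteCovs)) siteCovs@covariates,
                   if (!is.null(occCovs)) occCovs@covariates)
    bad <- setdiff(c(occNames, detNames), available)
    if (length(bad)) {
      configError(paste("covariate(s) not found in the supplied tables:",
                        paste(bad, collapse = ", ")))
    }
    if (sum(detectionArray(data)) == 0) configError("dataset holds no detections")

    screening <- NULL
    if (isTRUE(cfg$screen_collinearity) && !is.null(siteCovs) &&
        length(siteCovs@covariates) >= 2L) {
      say("screening site covariates for collinearity")
      screening <- screenCollinearity(siteCovs)
      keptOcc <- intersect(occNames, c(screening$retained,
                                       setdiff(occNames, siteCovs@covariates)))
      occNames <- keptOcc
    }
    if (!is.null(siteCovs)) siteCovs <- standardizeCovariates(siteCovs)
    if (!is.null(occCovs)) occCovs <- standardizeCovariates(occCovs)

    spec <- ModelSpec(occupancyCovariates = occNames,
                      detectionCovariates = detNames)
    mc <- cfg$mcmc %||% list()
    config <- McmcConfig(
      chains = mc$chains %||% 3L,
      iterations = mc$iterations %||% 150000L,
      burnin = mc$burnin %||% 50000L,
      thin = mc$thin %||% 100L,
      baseSeed = seed
    )

    say(sprintf("fitting MSOM: %d species, %d sites", length(speciesIds(data)),
                length(siteIds(data))))
    samples <- runMcmc(data, siteCovs, occCovs, spec, config)

    say("diagnostics and goodness-of-fit")
    rhatMax <- if (config@chains >= 2L) maxRhat(samples) else NA_real_
    rhatThreshold <- cfg$rhat_threshold %||% 1.1
    converged <- is.na(rhatMax) || rhatMax <= rhatThreshold
    gof <- bayesianPValue(samples, data, siteCovs, occCovs,
                          seed = deriveSeed(seed, 99L))

    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    outputs <- c(
      hyper_summary = file.path(outDir, "hyper_summary.csv"),
      species_summary = file.path(outDir, "species_summary.csv"),
      richness_sites = file.path(outDir, "richness_sites.csv"),
      fit = file.path(outDir, "fit"),
      manifest = file.path(outDir, "run_manifest.json")
    )

    hyperPars <- grep("^(mu|sigma)\\.", colnames(samples@draws[[1L]]),
                      value = TRUE)
    hs <- summarizePosterior(samples, hyperPars)
    utils::write.csv(hs, outputs["hyper_summary"], row.names = FALSE)

    counts <- detectionCounts(data)
    zAll <- if (length(samples@zDraws)) do.call(abind3, samples@zDraws)
    sp <- data.frame(
      species = counts$species,
      detections = counts$detections,
      naiveOccupancy = naiveOccupancy(data),
      meanOccupancy = if (!is.null(zAll)) apply(zAll, 1L, mean) else NA_real_,
      row.names = NULL, stringsAsFactors = FALSE
    )
    for (nm in occNames) {
      cls <- speciesEffectTable(samples, nm, "occupancy")
      sp[[paste0("effect_", nm)]] <- paste(cls$label, cls$sign)
    }
    utils::write.csv(sp, outputs["species_summary"], row.names = FALSE)

    rich <- estimatedRichness(samples, data)
    utils::write.csv(rich, outputs["richness_sites"], row.names = FALSE)
    writePosteriorSamples(samples, outputs["fit"])

    inputFiles <- paths[!is.na(paths)]
    manifest <- list(
      command = list(config = normalizePath(configPath), out_dir = outDir),
      input_digests = as.list(tools::md5sum(inputFiles)),
      seed = seed,
      chain_seeds = vapply(seq_len(config@chains), function(ch)
        deriveSeed(seed, ch), integer(1)),
      version = as.character(utils::packageVersion("msoccu")),
      model = list(occupancy_covariates = occNames,
                   detection_covariates = detNames),
      screening = if (!is.null(screening)) {
        list(retained = screening$retained, dropped = screening$dropped$name)
      },
      acceptance_rates = as.list(round(acceptanceRates(samples), 4)),
      max_rhat = rhatMax,
      converged = converged,
      bayes_p = bayesP(gof),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    jsonlite::write_json(manifest, outputs["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    if (!converged) {
      warning(sprintf("chains may not have converged: max R-hat %.3f > %.2f",
                      rhatMax, rhatThreshold))
      say(sprintf("WARNING: max R-hat %.3f exceeds %.2f", rhatMax, rhatThreshold))
    }
    list(status = 0L, message = "ok", manifest = manifest, outputs = outputs,
         samples = samples)
  },
  msoccuInputError = function(e) list(status = 2L, message = conditionMessage(e)),
  msoccuConfigError = function(e) list(status = 3L, message = conditionMessage(e)),
  error = function(e) list(status = 3L, message = conditionMessage(e))
  )
  result
}
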