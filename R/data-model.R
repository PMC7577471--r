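# Constructors, delimited-text I/O and covariate preparation.

#' Construct a DetectionData object
#'
#' @param x binary N x J x K array (species x site x occasion). Values on
#'   unobserved occasions are forced to 0.
#' @param mask binary J x K survey mask; default all surveyed.
#' @param species,sites,occasions axis labels; defaults are generated.
#' @return a validated \code{\linkS4class{DetectionData}}.
#' @export
detectionData <- function(x, mask = NULL, species = NULL, sites = NULL,
                          occasions = NULL) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a 3-d array (species x site x occasion)")
  if (is.null(mask)) mask <- matrix(1, d[2L], d[3L])
  mask <- matrix(as.numeric(mask), d[2L], d[3L])
  obs <- aperm(array(mask, c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  x <- array(as.numeric(x), d)
  x[obs == 0] <- 0
  new("DetectionData",
    x = x, mask = mask,
    species = as.character(species %||% sprintf("sp%02d", seq_len(d[1L]))),
    sites = as.character(sites %||% sprintf("site%02d", seq_len(d[2L]))),
    occasions = as.character(occasions %||% sprintf("occ%d", seq_len(d[3L])))
  )
}

#' Construct a CovariateTable
#'
#' @param values for site level: a J x C numeric matrix or a data.frame of
#'   numeric columns; for occasion level: a J x K x C array.
#' @param level \code{"site"} (default) or \code{"site_occasion"}.
#' @param covariates,sites,occasions labels; taken from dimnames/columns
#'   when available.
#' @return a validated \code{\linkS4class{CovariateTable}} (not standardized).
#' @export
covariateTable <- function(values, level = c("site", "site_occasion"),
                           covariates = NULL, sites = NULL, occasions = NULL) {
  level <- match.arg(level)
  if (level == "site") {
    if (is.data.frame(values)) {
      covariates <- covariates %||% names(values)
      values <- as.matrix(values)
    }
    covariates <- covariates %||% colnames(values) %||%
      sprintf("cov%d", seq_len(ncol(values)))
    sites <- sites %||% rownames(values) %||% sprintf("site%02d", seq_len(nrow(values)))
    values <- matrix(as.numeric(values), nrow(values), ncol(values))
    occasions <- character()
  } else {
    d <- dim(values)
    covariates <- covariates %||% dimnames(values)[[3L]] %||% sprintf("cov%d", seq_len(d[3L]))
    sites <- sites %||% dimnames(values)[[1L]] %||% sprintf("site%02d", seq_len(d[1L]))
    occasions <- occasions %||% dimnames(values)[[2L]] %||% sprintf("occ%d", seq_len(d[2L]))
    values <- array(as.numeric(values), d)
  }
  new("CovariateTable",
    values = values, level = level, covariates = as.character(covariates),
    sites = as.character(sites), occasions = as.character(occasions),
    standardized = FALSE, center = numeric(), scale = numeric()
  )
}

# ---- detection-record I/O ---------------------------------------------------

#' Read long-format detection records
#'
#' Reads a delimited table with columns \code{species,site,occasion,detected}
#' (detected in \{0,1\}) into a dense \code{DetectionData}. Which
#' (site, occasion) cells count as surveyed is governed by the occasion
#' manifest: an absent record row for a surveyed occasion means
#' non-detection; occasions absent from the manifest are treated as not
#' surveyed and any records there are ignored. Without a manifest, a
#' (site, occasion) cell counts as surveyed if any record row mentions it.
#'
#' @param path CSV path of detection records.
#' @param manifest optional CSV path or data.frame with columns
#'   \code{site,occasion} listing surveyed occasions per site.
#' @return a \code{\linkS4class{DetectionData}}.
#' @export
readDetectionRecords <- function(path, manifest = NULL) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "site", "occasion", "detected")
  if (!all(need %in% names(rec))) {
    stop("detection records need columns: ", paste(need, collapse = ", "))
  }
  if (!all(rec$detected %in% c(0, 1))) {
    stop("'detected' must be 0 or 1")
  }
  key <- paste(rec$species, rec$site, rec$occasion, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(rec$detected, key, function(v) length(unique(v)))
    if (any(agg > 1L)) {
      bad <- names(agg)[agg > 1L][1L]
      stop("conflicting duplicate record for (species,site,occasion): ",
           gsub("\r", ", ", bad))
    }
    rec <- rec[!duplicated(key), , drop = FALSE]
  }
  man <- NULL
  if (!is.null(manifest)) {
    man <- if (is.data.frame(manifest)) manifest else utils::read.csv(manifest, stringsAsFactors = FALSE)
    if (!all(c("site", "occasion") %in% names(man))) {
      stop("occasion manifest needs columns site, occasion")
    }
  }
  species <- sort(unique(as.character(rec$species)))
  sites <- sort(unique(c(as.character(rec$site), as.character(man$site))))
  occasions <- sort(unique(c(as.character(rec$occasion), as.character(man$occasion))))
  N <- length(species); J <- length(sites); K <- length(occasions)
  mask <- matrix(0, J, K)
  if (is.null(man)) {
    mask[cbind(match(rec$site, sites), match(rec$occasion, occasions))] <- 1
  } else {
    mask[cbind(match(man$site, sites), match(man$occasion, occasions))] <- 1
  }
  x <- array(0, c(N, J, K))
  hit <- rec$detected == 1
  x[cbind(match(rec$species, species)[hit],
          match(rec$site, sites)[hit],
          match(rec$occasion, occasions)[hit])] <- 1
  detectionData(x, mask, species, sites, occasions)
}

#' Write detection records and their occasion manifest
#'
#' Writes explicit rows for every surveyed (species, site, occasion) cell
#' plus a site/occasion manifest, so \code{\link{readDetectionRecords}}
#' reproduces the object losslessly.
#'
#' @param data a \code{DetectionData}.
#' @param path output CSV path for the records.
#' @param manifestPath output CSV path for the occasion manifest.
#' @return invisibly, the record data.frame.
#' @export
writeDetectionRecords <- function(data, path, manifestPath) {
  d <- dim(data@x)
  obs <- which(data@mask == 1, arr.ind = TRUE)
  man <- data.frame(site = data@sites[obs[, 1L]],
                    occasion = data@occasions[obs[, 2L]])
  man <- man[order(man$site, man$occasion), , drop = FALSE]
  idx <- expand.grid(i = seq_len(d[1L]), jk = seq_len(nrow(obs)))
  rec <- data.frame(
    species = data@species[idx$i],
    site = data@sites[obs[idx$jk, 1L]],
    occasion = data@occasions[obs[idx$jk, 2L]],
    detected = data@x[cbind(idx$i, obs[idx$jk, 1L], obs[idx$jk, 2L])]
  )
  rec <- rec[order(rec$species, rec$site, rec$occasion), , drop = FALSE]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(man, manifestPath, row.names = FALSE, quote = FALSE)
  invisible(rec)
}

#' Read a covariate table from CSV
#'
#' Site-level files carry a \code{site} column plus one numeric column per
#' covariate; occasion-level files carry \code{site,occasion} key columns.
#' Missing (site, occasion) combinations become \code{NA}.
#'
#' @param path CSV path.
#' @param level \code{"site"} or \code{"site_occasion"}.
#' @return a \code{\linkS4class{CovariateTable}}.
#' @export
readCovariateTable <- function(path, level = c("site", "site_occasion")) {
  level <- match.arg(level)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (level == "site") {
    if (!"site" %in% names(tab)) stop("site-level covariate file needs a 'site' column")
    covs <- setdiff(names(tab), "site")
    m <- as.matrix(tab[covs])
    rownames(m) <- NULL
    covariateTable(m, "site", covariates = covs, sites = as.character(tab$site))
  } else {
    if (!all(c("site", "occasion") %in% names(tab))) {
      stop("occasion-level covariate file needs 'site' and 'occasion' columns")
    }
    covs <- setdiff(names(tab), c("site", "occasion"))
    sites <- sort(unique(as.character(tab$site)))
    occasions <- sort(unique(as.character(tab$occasion)))
    a <- array(NA_real_, c(length(sites), length(occasions), length(covs)))
    ji <- match(tab$site, sites); ki <- match(tab$occasion, occasions)
    for (ci in seq_along(covs)) {
      a[cbind(ji, ki, ci)] <- as.numeric(tab[[covs[ci]]])
    }
    covariateTable(a, "site_occasion", covariates = covs, sites = sites,
                   occasions = occasions)
  }
}

#' Write a covariate table to CSV
#'
#' @param table a \code{CovariateTable}.
#' @param path output CSV path.
#' @return invisibly, the written data.frame.
#' @export
writeCovariateTable <- function(table, path) {
  if (table@level == "site") {
    df <- data.frame(site = table@sites)
    for (ci in seq_along(table@covariates)) df[[table@covariates[ci]]] <- table@values[, ci]
  } else {
    grid <- expand.grid(site = table@sites, occasion = table@occasions,
                        stringsAsFactors = FALSE)
    df <- grid[order(grid$site, grid$occasion), , drop = FALSE]
    ji <- match(df$site, table@sites); ki <- match(df$occasion, table@occasions)
    for (ci in seq_along(table@covariates)) {
      df[[table@covariates[ci]]] <- table@values[cbind(ji, ki, ci)]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

# ---- covariate preparation --------------------------------------------------

#' Standardize covariates to mean 0, sd 1
#'
#' Centers and scales each covariate over its non-missing entries using the
#' sample standard deviation (n - 1 denominator). Scaling is composed with
#' any previously recorded scaling, so \code{\link{unstandardizeCovariates}}
#' always recovers the original raw values; re-standardizing an already
#' standardized table leaves the values unchanged.
#'
#' @param table a \code{CovariateTable}.
#' @return a standardized \code{CovariateTable} with recorded center/scale.
#' @export
standardizeCovariates <- function(table) {
  v <- table@values
  C <- length(table@covariates)
  ctr <- numeric(C); scl <- numeric(C)
  for (ci in seq_len(C)) {
    col <- if (table@level == "site") v[, ci] else v[, , ci]
    ok <- is.finite(col)
    m <- mean(col[ok]); s <- stats::sd(col[ok])
    if (!is.finite(s) || s <= 0) {
      stop("cannot standardize constant covariate '", table@covariates[ci], "'")
    }
    ctr[ci] <- m; scl[ci] <- s
    if (table@level == "site") v[, ci] <- (v[, ci] - m) / s else v[, , ci] <- (v[, , ci] - m) / s
  }
  if (table@standardized) {
    ctr <- table@center[table@covariates] + table@scale[table@covariates] * ctr
    scl <- table@scale[table@covariates] * scl
  }
  names(ctr) <- names(scl) <- table@covariates
  methods::initialize(table, values = v, standardized = TRUE,
                      center = ctr, scale = scl)
}

#' Invert standardization using the recorded scaling
#'
#' @param table a standardized \code{CovariateTable}.
#' @return the table on its original raw scale.
#' @export
unstandardizeCovariates <- function(table) {
  if (!table@standardized) return(table)
  v <- table@values
  for (ci in seq_along(table@covariates)) {
    m <- table@center[table@covariates[ci]]
    s <- table@scale[table@covariates[ci]]
    if (table@level == "site") v[, ci] <- v[, ci] * s + m else v[, , ci] <- v[, , ci] * s + m
  }
  methods::initialize(table, values = v, standardized = FALSE,
                      center = numeric(), scale = numeric())
}

#' Standardize a prediction grid with the scaling of a fit
#'
#' @param table raw-scale site-level \code{CovariateTable} (e.g. a grid).
#' @param scaling list with named \code{center} and \code{scale} vectors,
#'   e.g. one element of \code{scalingInfo(fit)}.
#' @return standardized table on the fit's scale.
#' @export
applyScaling <- function(table, scaling) {
  v <- table@values
  ctr <- numeric(0); scl <- numeric(0)
  for (ci in seq_along(table@covariates)) {
    nm <- table@covariates[ci]
    if (!nm %in% names(scaling$center)) {
      stop("no recorded scaling for covariate '", nm, "'")
    }
    if (table@level == "site") {
      v[, ci] <- (v[, ci] - scaling$center[nm]) / scaling$scale[nm]
    } else {
      v[, , ci] <- (v[, , ci] - scaling$center[nm]) / scaling$scale[nm]
    }
    ctr[nm] <- scaling$center[nm]; scl[nm] <- scaling$scale[nm]
  }
  methods::initialize(table, values = v, standardized = TRUE,
                      center = ctr, scale = scl)
}

#' Screen covariates for collinearity
#'
#' Iteratively discards covariates until every retained pair has Pearson
#' \code{|r| <= rMax} and every retained covariate has variance inflation
#' factor \code{VIF <= vifMax}, where \code{VIF_m = 1 / (1 - R^2_m)} from an
#' ordinary least-squares regression of covariate m on all other current
#' candidates. At each step the covariate with the most \code{|r|}-threshold
#' partners is dropped; ties break by higher VIF, then alphabetically.
#'
#' @param table a site-level \code{CovariateTable} with >= 2 covariates and
#'   >= 3 rows; the number of rows must be at least the number of covariates
#'   (otherwise VIF is undefined).
#' @param rMax correlation threshold (default 0.60).
#' @param vifMax VIF threshold (default 3).
#' @return a \code{ScreeningReport}: list with \code{pairwiseR} (initial
#'   correlation matrix), \code{vif} (final VIFs, NA for dropped),
#'   \code{retained}, and \code{dropped} (data.frame name/reason).
#' @export
screenCollinearity <- function(table, rMax = 0.60, vifMax = 3) {
  if (table@level != "site") stop("collinearity screening expects a site-level table")
  m <- table@values
  colnames(m) <- table@covariates
  if (ncol(m) < 2L) stop("need at least 2 covariates")
  if (nrow(m) < 3L) stop("need at least 3 observations")
  if (nrow(m) < ncol(m)) stop("fewer rows than covariates: VIF undefined")
  pairwiseR <- stats::cor(m, use = "pairwise.complete.obs")
  dropped <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  cand <- colnames(m)
  repeat {
    if (length(cand) < 2L) break
    r <- stats::cor(m[, cand, drop = FALSE], use = "pairwise.complete.obs")
    vif <- vapply(cand, function(nm) vifOne(m[, cand, drop = FALSE], nm), numeric(1))
    partners <- colSums(abs(r) > rMax & row(r) != col(r))
    if (all(partners == 0L) && all(vif <= vifMax)) break
    ord <- order(-partners, -vif, cand)
    worst <- cand[ord[1L]]
    reason <- if (partners[worst] > 0L) "r-rule" else "VIF-rule"
    dropped <- rbind(dropped, data.frame(name = worst, reason = reason,
                                         stringsAsFactors = FALSE))
    cand <- setdiff(cand, worst)
  }
  vifFinal <- rep(NA_real_, ncol(m))
  names(vifFinal) <- colnames(m)
  if (length(cand) >= 2L) {
    vifFinal[cand] <- vapply(cand, function(nm) vifOne(m[, cand, drop = FALSE], nm),
                             numeric(1))
  } else if (length(cand) == 1L) {
    vifFinal[cand] <- 1
  }
  structure(
    list(pairwiseR = pairwiseR, vif = vifFinal, retained = cand,
         dropped = dropped, rMax = rMax, vifMax = vifMax),
    class = "ScreeningReport"
  )
}

# VIF of one column regressed on the remaining columns (with intercept).
vifOne <- function(m, name) {
  y <- m[, name]
  X <- m[, setdiff(colnames(m), name), drop = FALSE]
  ok <- stats::complete.cases(cbind(y, X))
  fit <- stats::lm.fit(cbind(1, X[ok, , drop = FALSE]), y[ok])
  rss <- sum(fit$residuals^2)
  tss <- sum((y[ok] - mean(y[ok]))^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
}

#' @export
print.ScreeningReport <- function(x, ...) {
  cat(sprintf("Collinearity screening (|r| <= %.2f, VIF <= %.2f)\n", x$rMax, x$vifMax))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("  dropped: ",
        paste(sprintf("%s (%s)", x$dropped$name, x$dropped$reason), collapse = ", "),
        "\n", sep = "")
  } else {
    cat("  dropped: none\n")
  }
  invisible(x)
}

# ---- habitat pooling --------------------------------------------------------

habitatSourceColumns <- list(
  forest = c("semi_evergreen_forest", "moist_deciduous_forest", "mangrove"),
  degraded_forest = c("scrub_forest", "grassland"),
  anthropogenic = c("settlement", "agriculture")
)

#' Pool seven land-cover classes into three habitat categories
#'
#' Sums per-site cover fractions of the seven source land-cover classes
#' into three homogeneous categories: forest (semi-evergreen + moist
#' deciduous + mangrove), degraded forest (scrub + grassland) and
#' anthropogenic habitat (settlement + agriculture). Total cover per site
#' is conserved.
#'
#' @param table site-level \code{CovariateTable} with columns
#'   \code{semi_evergreen_forest, moist_deciduous_forest, mangrove,
#'   scrub_forest, grassland, settlement, agriculture}.
#' @return site-level \code{CovariateTable} with columns \code{forest},
#'   \code{degraded_forest}, \code{anthropogenic}.
#' @export
poolHabitatCovers <- function(table) {
  if (table@level != "site") stop("habitat pooling expects a site-level table")
  need <- unlist(habitatSourceColumns, use.names = FALSE)
  missing <- setdiff(need, table@covariates)
  if (length(missing)) {
    stop("missing required cover column(s): ", paste(missing, collapse = ", "))
  }
  m <- table@values
  colnames(m) <- table@covariates
  pooled <- vapply(habitatSourceColumns,
                   function(cols) rowSums(m[, cols, drop = FALSE]),
                   numeric(nrow(m)))
  pooled <- matrix(pooled, nrow = nrow(m),
                   dimnames = list(NULL, names(habitatSourceColumns)))
  covariateTable(pooled, "site", sites = table@sites)
}

#' Assign each site a pooled habitat class
#'
#' The class is the pooled category with the largest cover fraction; ties
#' break in the order forest, degraded_forest, anthropogenic.
#'
#' @param pooled output of \code{\link{poolHabitatCovers}} (or any
#'   site-level table with the three pooled columns).
#' @param sourceFractions optional site-level table of the seven source
#'   fractions, carried along for reference.
#' @return a \code{HabitatClassTable}: data.frame with columns \code{site}
#'   and \code{class}, plus a \code{sourceFractions} attribute when given.
#' @export
habitatClasses <- function(pooled, sourceFractions = NULL) {
  classes <- names(habitatSourceColumns)
  missing <- setdiff(classes, pooled@covariates)
  if (length(missing)) stop("pooled table lacks column(s): ", paste(missing, collapse = ", "))
  m <- pooled@values[, match(classes, pooled@covariates), drop = FALSE]
  cls <- classes[apply(m, 1L, which.max)]
  out <- data.frame(site = pooled@sites, class = cls, stringsAsFactors = FALSE)
  if (!is.null(sourceFractions)) attr(out, "sourceFractions") <- sourceFractions
  class(out) <- c("HabitatClassTable", "data.frame")
  out
}

# ---- descriptive summaries --------------------------------------------------

#' Per-species detection totals and naive site counts
#'
#' @param data a \code{DetectionData}.
#' @return data.frame with one row per species: total detections over
#'   surveyed occasions and the number of sites with at least one detection.
#' @export
detectionCounts <- function(data) {
  d <- dim(data@x)
  perSite <- apply(data@x, c(1L, 2L), sum)
  data.frame(
    species = data@species,
    detections = as.integer(rowSums(perSite)),
    sitesWithDetection = as.integer(rowSums(perSite > 0)),
    stringsAsFactors = FALSE
  )
}

#' Naive occupancy per species
#'
#' Fraction of sites with at least one detection, uncorrected for imperfect
#' detection.
#'
#' @param data a \code{DetectionData}.
#' @return named numeric vector (one value per species) in [0, 1].
#' @export
naiveOccupancy <- function(data) {
  counts <- detectionCounts(data)
  stats::setNames(counts$sitesWithDetection / length(data@sites), counts$species)
}

#' Observed species richness per site or group
#'
#' Counts species with at least one detection in each group of sites.
#'
#' @param data a \code{DetectionData}.
#' @param grouping optional named character vector mapping every site id to
#'   a group label (e.g. a habitat class); default: each site is its own
#'   group.
#' @return named integer vector of richness per group.
#' @export
observedRichness <- function(data, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- stats::setNames(data@sites, data@sites)
  }
  missing <- setdiff(data@sites, names(grouping))
  if (length(missing)) {
    stop("grouping lacks site(s): ", paste(missing, collapse = ", "))
  }
  detected <- apply(data@x, c(1L, 2L), sum) > 0   # N x J
  groups <- unique(grouping[data@sites])
  out <- vapply(groups, function(g) {
    js <- which(grouping[data@sites] == g)
    sum(rowSums(detected[, js, drop = FALSE]) > 0)
  }, integer(1))
  stats::setNames(as.integer(out), groups)
}

#' Import a converted supplementary-data directory
#'
#' Thin wrapper for field datasets exported to the package's long CSV
#' layout: \code{detections.csv} (species,site,occasion,detected),
#' \code{manifest.csv} (site,occasion), \code{site_covariates.csv} and
#' optionally \code{occasion_covariates.csv}. Spreadsheet workbooks must
#' first be exported sheet-by-sheet to these CSVs (see the package README).
#'
#' @param dir directory containing the CSV files.
#' @return list with elements \code{data}, \code{siteCovariates} and
#'   (possibly NULL) \code{occasionCovariates}.
#' @export
importSupplementaryData <- function(dir) {
  det <- file.path(dir, "detections.csv")
  man <- file.path(dir, "manifest.csv")
  scov <- file.path(dir, "site_covariates.csv")
  ocov <- file.path(dir, "occasion_covariates.csv")
  for (f in c(det, man, scov)) {
    if (!file.exists(f)) stop("missing input file: ", f)
  }
  list(
    data = readDetectionRecords(det, man),
    siteCovariates = readCovariateTable(scov, "site"),
    occasionCovariates = if (file.exists(ocov)) {
      readCovariateTable(ocov, "site_occasion")
    } else NULL
  )
}
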