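## Plain-text raster and table I/O.
##
## Binary presence layers are stored as single-band TIFF (values 0/1).
## Continuous rasters (current, climate) are stored as TSV matrices
## with a small '#'-prefixed header carrying the grid metadata, since
## the TIFF writer only represents values in [0, 1]. Tables are CSV.

#' Write / read a binary landscape
#'
#' One TIFF per class, named \code{<stem>_broadleaf.tif} and
#' \code{<stem>_conifer.tif}, plus \code{<stem>_meta.yaml} with the
#' resolution, origin and period.
#'
#' @param x a \code{LandscapeRaster}.
#' @param stem path stem (no extension).
#' @return \code{writeLandscape}: the stem, invisibly;
#'   \code{readLandscape}: a \code{LandscapeRaster}.
#' @export
writeLandscape <- function(x, stem) {
  stopifnot(is(x, "LandscapeRaster"))
  tiff::writeTIFF(x@broadleaf, paste0(stem, "_broadleaf.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(x@conifer, paste0(stem, "_conifer.tif"),
                  bits.per.sample = 8L)
  yaml::write_yaml(list(fineRes = x@fineRes, origin = x@origin,
                        period = x@period),
                   paste0(stem, "_meta.yaml"))
  invisible(stem)
}

#' @rdname writeLandscape
#' @export
readLandscape <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, "_meta.yaml"))
  bl <- round(tiff::readTIFF(paste0(stem, "_broadleaf.tif")))
  con <- round(tiff::readTIFF(paste0(stem, "_conifer.tif")))
  new("LandscapeRaster", broadleaf = bl, conifer = con,
      fineRes = meta$fineRes, origin = as.numeric(meta$origin),
      period = meta$period)
}

## Matrix <-> TSV with '# key: value' header lines.
writeMatrixTSV <- function(m, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    cat(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")),
        "\n", file = con, sep = "")
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

readMatrixTSV <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^# *", "", lines[h])
    k <- sub(":.*$", "", kv)
    meta[[k]] <- strsplit(sub("^[^:]*: *", "", kv), " ")[[1]]
  }
  m <- as.matrix(utils::read.table(text = lines[setdiff(seq_along(lines),
                                                        hdr)],
                                   sep = "\t"))
  dimnames(m) <- NULL
  list(matrix = m, meta = meta)
}

#' Write / read a cumulative current map
#'
#' Stored as a TSV matrix with header metadata (radius, block size,
#' resolution).
#'
#' @param x a \code{CurrentMap}.
#' @param path output path.
#' @return \code{writeCurrentMap}: the path, invisibly;
#'   \code{readCurrentMap}: a \code{CurrentMap}.
#' @export
writeCurrentMap <- function(x, path) {
  stopifnot(is(x, "CurrentMap"))
  writeMatrixTSV(x@current, path,
                 list(radiusM = x@radiusM, blockSize = x@blockSize,
                      fineRes = x@fineRes))
  invisible(path)
}

#' @rdname writeCurrentMap
#' @export
readCurrentMap <- function(path) {
  r <- readMatrixTSV(path)
  new("CurrentMap", current = r$matrix,
      radiusM = as.numeric(r$meta$radiusM),
      blockSize = as.numeric(r$meta$blockSize),
      fineRes = as.numeric(r$meta$fineRes))
}

#' Write / read a climate stack
#'
#' One TSV per surface, \code{<stem>_<var>.tsv}.
#'
#' @param x a \code{ClimateStack}.
#' @param stem path stem.
#' @return \code{writeClimate}: the stem, invisibly;
#'   \code{readClimate}: a \code{ClimateStack}.
#' @export
writeClimate <- function(x, stem) {
  stopifnot(is(x, "ClimateStack"))
  for (v in names(x@layers))
    writeMatrixTSV(x@layers[[v]], paste0(stem, "_", v, ".tsv"),
                   list(period = x@period, var = v))
  invisible(stem)
}

#' @rdname writeClimate
#' @export
readClimate <- function(stem) {
  layers <- lapply(.CLIMATE_VARS, function(v)
    readMatrixTSV(paste0(stem, "_", v, ".tsv"))$matrix)
  names(layers) <- .CLIMATE_VARS
  per <- readMatrixTSV(paste0(stem, "_", .CLIMATE_VARS[1], ".tsv"))
  new("ClimateStack", layers = layers,
      period = as.character(per$meta$period))
}

#' Write / read occurrence records
#'
#' CSV with columns species_id, scheme_id, cell_id, date (ISO-8601),
#' precision_m.
#'
#' @param records records data.frame.
#' @param path CSV path.
#' @return \code{writeRecords}: the path, invisibly;
#'   \code{readRecords}: the records data.frame.
#' @export
writeRecords <- function(records, path) {
  out <- records
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  r$date <- as.Date(r$date)
  r
}

#' Write / read a covariate grid
#'
#' CSV of the covariate table plus a YAML sidecar
#' (\code{<path>.meta.yaml}) with geometry and any standardisation
#' parameters.
#'
#' @param x a \code{CovariateGrid}.
#' @param path CSV path.
#' @return \code{writeCovariateGrid}: the path, invisibly;
#'   \code{readCovariateGrid}: a \code{CovariateGrid}.
#' @export
writeCovariateGrid <- function(x, path) {
  stopifnot(is(x, "CovariateGrid"))
  utils::write.csv(x@data, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(coarseRes = x@coarseRes,
                        dims = as.integer(x@dims),
                        standardisation = x@standardisation),
                   paste0(path, ".meta.yaml"), precision = 15L)
  invisible(path)
}

#' @rdname writeCovariateGrid
#' @export
readCovariateGrid <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  std <- meta$standardisation
  if (is.null(std)) std <- list()
  new("CovariateGrid", data = dat, coarseRes = meta$coarseRes,
      dims = as.integer(meta$dims), standardisation = std)
}

#' Collect species model results into a long table
#'
#' One row per (species, effect): estimates, interval, convergence and
#' variant — the exchange format between the occurrence-model stage and
#' the meta-analysis.
#'
#' @param results list of \code{SpeciesModelResult} objects.
#' @return data.frame.
#' @export
resultsTable <- function(results) {
  rows <- lapply(results, function(r) {
    if (!isConverged(r))
      return(data.frame(species_id = r@speciesId,
                        scheme_id = r@schemeId, variant = r@variant,
                        effect = NA_character_, mean = NA_real_,
                        sd = NA_real_, `q2.5` = NA_real_,
                        `q97.5` = NA_real_, converged = FALSE,
                        check.names = FALSE))
    cbind(data.frame(species_id = r@speciesId, scheme_id = r@schemeId,
                     variant = r@variant, stringsAsFactors = FALSE),
          r@summary, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
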