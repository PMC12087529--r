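## Aggregation of fine-grid layers to the coarse analysis grid, and
## covariate standardisation.
##
## Coordinate convention: row-major coarse cells with 0-based indices;
## coarse cell (i, j) covers fine-pixel rows [i*k, (i+1)*k) and columns
## [j*k, (j+1)*k), k = coarseRes / fineRes. Cell id = i * ncol + j.

#' Aggregate fine-grid cover and current to the coarse grid
#'
#' Per coarse cell: class cover is the fraction of fine pixels that are
#' woodland of that class; connectivity is the median cumulative
#' current over all fine pixels in the cell (woodland and matrix).
#' Climate surfaces are already on the coarse grid and are carried
#' through.
#'
#' @param current a \code{CurrentMap}.
#' @param landscape the \code{LandscapeRaster} of the same period.
#' @param climate a \code{ClimateStack} on the coarse grid.
#' @param coarseRes coarse cell edge length (m); must be an integer
#'   multiple of the fine resolution and divide the fine grid evenly.
#' @return a \code{\link{CovariateGrid-class}} in natural units.
#' @export
aggregateCovariates <- function(current, landscape, climate, coarseRes) {
  stopifnot(is(current, "CurrentMap"), is(landscape, "LandscapeRaster"),
            is(climate, "ClimateStack"))
  fineRes <- current@fineRes
  k <- coarseRes / fineRes
  if (abs(k - round(k)) > 1e-9)
    stop("coarseRes must be an integer multiple of the fine resolution")
  k <- as.integer(round(k))
  cm <- current@current
  nr <- nrow(cm); nc <- ncol(cm)
  if (nr %% k != 0 || nc %% k != 0)
    stop("fine grid shape is not divisible by the aggregation factor")
  nrC <- nr %/% k; ncC <- nc %/% k
  if (!identical(dim(climate@layers[[1]]), c(nrC, ncC)))
    stop("climate surfaces must match the coarse grid shape")
  if (landscape@period != climate@period)
    stop("landscape and climate periods differ")

  blockIdx <- function() {
    rw <- (seq_len(nr) - 1L) %/% k       # 0-based coarse row per fine row
    cl <- (seq_len(nc) - 1L) %/% k
    outer(rw, cl, function(a, b) a * ncC + b)  # row-major cell id
  }
  bid <- as.vector(blockIdx())

  blockStat <- function(m, f) {
    s <- vapply(split(as.vector(m), bid), f, 0)
    s[order(as.integer(names(s)))]
  }
  blCover <- blockStat(landscape@broadleaf, mean)
  conCover <- blockStat(landscape@conifer, mean)
  conn <- blockStat(cm, stats::median)

  ids <- sort(unique(bid))
  dat <- data.frame(
    cell = ids,
    row = ids %/% ncC,
    col = ids %% ncC,
    period = landscape@period,
    bl_cover = as.numeric(blCover),
    con_cover = as.numeric(conCover),
    conn = as.numeric(conn),
    stringsAsFactors = FALSE)
  for (v in .CLIMATE_VARS) {
    lay <- climate@layers[[v]]
    dat[[v]] <- lay[cbind(dat$row + 1L, dat$col + 1L)]
  }
  new("CovariateGrid", data = dat, coarseRes = coarseRes,
      dims = c(nrC, ncC), standardisation = list())
}

#' Stack the two period grids
#'
#' @param p1,p2 \code{CovariateGrid} objects for periods P1 and P2 with
#'   identical geometry, both in natural units.
#' @return a single \code{CovariateGrid} with one row per (cell, period).
#' @export
combineCovariateGrids <- function(p1, p2) {
  stopifnot(is(p1, "CovariateGrid"), is(p2, "CovariateGrid"))
  if (!identical(p1@dims, p2@dims) || p1@coarseRes != p2@coarseRes)
    stop("grids have mismatched geometry")
  if (length(p1@standardisation) || length(p2@standardisation))
    stop("combine grids before standardising")
  if (identical(unique(p1@data$period), unique(p2@data$period)))
    stop("grids must come from different periods")
  new("CovariateGrid", data = rbind(p1@data, p2@data),
      coarseRes = p1@coarseRes, dims = p1@dims,
      standardisation = list())
}

#' Standardise covariates to mean 0, SD 1
#'
#' Centres and scales every covariate using the mean and population
#' (divide-by-n) standard deviation pooled over both periods across the
#' standardisation domain. The parameters are stored on the grid so
#' effects can be back-transformed to natural units. Standardising an
#' already standardised grid leaves values unchanged and composes the
#' stored parameters.
#'
#' @param grid a \code{CovariateGrid}.
#' @param domainCells optional integer vector of cell ids defining the
#'   standardisation domain (default: all cells).
#' @return the standardised \code{CovariateGrid}.
#' @export
standardiseGrid <- function(grid, domainCells = NULL) {
  stopifnot(is(grid, "CovariateGrid"))
  dat <- grid@data
  rows <- if (is.null(domainCells)) seq_len(nrow(dat)) else
    which(dat$cell %in% domainCells)
  if (length(rows) < 2)
    stop("standardisation domain must contain at least 2 rows")
  old <- grid@standardisation
  pars <- list()
  for (v in .COVARIATE_VARS) {
    mu <- mean(dat[[v]][rows])
    sdv <- popSd(dat[[v]][rows])
    if (sdv < .Machine$double.eps)
      stop("variable '", v, "' is constant over the domain; ",
           "cannot standardise")
    dat[[v]] <- (dat[[v]] - mu) / sdv
    if (!is.null(old[[v]])) {
      # compose with the earlier transformation
      pars[[v]] <- list(mean = old[[v]]$mean + old[[v]]$sd * mu,
                        sd = old[[v]]$sd * sdv)
    } else {
      pars[[v]] <- list(mean = mu, sd = sdv)
    }
  }
  new("CovariateGrid", data = dat, coarseRes = grid@coarseRes,
      dims = grid@dims, standardisation = pars)
}

#' Convert between natural and standardised units
#'
#' @param std standardisation list as stored on a standardised
#'   \code{CovariateGrid} (see \code{\link{standardisation}}).
#' @param var variable name.
#' @param values numeric values to convert.
#' @return converted values.
#' @export
toStandard <- function(std, var, values) {
  p <- std[[var]]
  if (is.null(p)) stop("no standardisation parameters for '", var, "'")
  (values - p$mean) / p$sd
}

#' @rdname toStandard
#' @export
toNatural <- function(std, var, values) {
  p <- std[[var]]
  if (is.null(p)) stop("no standardisation parameters for '", var, "'")
  p$mean + p$sd * values
}
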