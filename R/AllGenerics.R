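#' @include AllClasses.R
NULL

#' Fraction of pixels that are woodland
#'
#' @param x a \code{LandscapeRaster}.
#' @param class \code{"broadleaf"}, \code{"conifer"} or \code{"total"}.
#' @return realised cover proportion in [0, 1].
#' @export
setGeneric("coverFraction", function(x, class = "total")
  standardGeneric("coverFraction"))

#' Extract a binary woodland layer
#' @param x a \code{LandscapeRaster}.
#' @param class \code{"broadleaf"} or \code{"conifer"}.
#' @return binary matrix.
#' @export
setGeneric("landscapeMatrix", function(x, class = "broadleaf")
  standardGeneric("landscapeMatrix"))

#' Period label of an object
#' @param x an object carrying a period slot.
#' @return \code{"P1"} or \code{"P2"}.
#' @export
setGeneric("periodLabel", function(x) standardGeneric("periodLabel"))

#' Cumulative current matrix
#' @param x a \code{CurrentMap}.
#' @return numeric matrix of cumulative current.
#' @export
setGeneric("currentMatrix", function(x) standardGeneric("currentMatrix"))

#' Covariate table of a grid
#' @param x a \code{CovariateGrid}.
#' @return data.frame, one row per (cell, period).
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' Standardisation parameters
#' @param x a \code{CovariateGrid}.
#' @return named list of per-variable list(mean, sd); empty for a grid
#'   still in natural units.
#' @export
setGeneric("standardisation", function(x) standardGeneric("standardisation"))

#' Posterior summary table of fixed effects
#' @param x a \code{SpeciesModelResult} or \code{MetaResult}.
#' @return data.frame of posterior summaries.
#' @export
setGeneric("effectSummary", function(x) standardGeneric("effectSummary"))

#' Convergence flag
#' @param x a model result.
#' @return logical.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Posterior draws of a meta-analysis fit
#' @param x a \code{MetaResult}.
#' @return named list of numeric vectors (mu, tau_species, tau_scheme).
#' @export
setGeneric("metaDraws", function(x) standardGeneric("metaDraws"))

#' Prediction grid of a surface
#' @param x a \code{PredictionSurface}.
#' @return data.frame of grid predictions.
#' @export
setGeneric("surfaceGrid", function(x) standardGeneric("surfaceGrid"))
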