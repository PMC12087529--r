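#' @include AllGenerics.R
NULL

#' @rdname coverFraction
setMethod("coverFraction", "LandscapeRaster", function(x, class = "total") {
  class <- match.arg(class, c("total", "broadleaf", "conifer"))
  m <- switch(class,
    broadleaf = x@broadleaf,
    conifer   = x@conifer,
    total     = x@broadleaf + x@conifer)
  mean(m != 0)
})

#' @rdname landscapeMatrix
setMethod("landscapeMatrix", "LandscapeRaster", function(x, class = "broadleaf") {
  class <- match.arg(class, c("broadleaf", "conifer"))
  slot(x, class)
})

#' @rdname periodLabel
setMethod("periodLabel", "LandscapeRaster", function(x) x@period)
#' @rdname periodLabel
setMethod("periodLabel", "ClimateStack", function(x) x@period)

#' @rdname currentMatrix
setMethod("currentMatrix", "CurrentMap", function(x) x@current)

#' @rdname covariates
setMethod("covariates", "CovariateGrid", function(x) x@data)

#' @rdname standardisation
setMethod("standardisation", "CovariateGrid", function(x) x@standardisation)

#' @rdname effectSummary
setMethod("effectSummary", "SpeciesModelResult", function(x) x@summary)
#' @rdname effectSummary
setMethod("effectSummary", "MetaResult", function(x) x@summary)

#' @rdname isConverged
setMethod("isConverged", "SpeciesModelResult", function(x) x@converged)
#' @rdname isConverged
setMethod("isConverged", "MetaResult", function(x) x@converged)

#' @rdname metaDraws
setMethod("metaDraws", "MetaResult", function(x) x@draws)

#' @rdname surfaceGrid
setMethod("surfaceGrid", "PredictionSurface", function(x) x@grid)

setMethod("show", "LandscapeRaster", function(object) {
  d <- dim(object@broadleaf)
  cat("LandscapeRaster:", d[1], "x", d[2], "pixels at",
      object@fineRes, "m, period", object@period, "\n")
  cat(sprintf("  broadleaf cover %.3f, conifer cover %.3f\n",
              coverFraction(object, "broadleaf"),
              coverFraction(object, "conifer")))
})

setMethod("show", "ClimateStack", function(object) {
  d <- dim(object@layers[[1]])
  cat("ClimateStack:", length(object@layers), "surfaces on a",
      d[1], "x", d[2], "grid, period", object@period, "\n")
})

setMethod("show", "ResistanceSurface", function(object) {
  cat("ResistanceSurface:", nrow(object@resistance), "x",
      ncol(object@resistance), "pixels;",
      sum(object@sourceMask), "source (woodland) pixels;",
      "resistance range", paste(range(object@resistance), collapse = "-"),
      "\n")
})

setMethod("show", "CurrentMap", function(object) {
  cat(sprintf(
    "CurrentMap: %d x %d pixels, radius %g m, block size %d\n",
    nrow(object@current), ncol(object@current), object@radiusM,
    as.integer(object@blockSize)))
  cat(sprintf("  cumulative current: max %.4g, mean %.4g\n",
              max(object@current), mean(object@current)))
})

setMethod("show", "CovariateGrid", function(object) {
  cat("CovariateGrid:", object@dims[1], "x", object@dims[2],
      "coarse cells at", object@coarseRes, "m;",
      nrow(object@data), "rows (cell x period);",
      if (length(object@standardisation)) "standardised" else "natural units",
      "\n")
})

setMethod("show", "TruthParams", function(object) {
  cat("TruthParams (logit scale):\n")
  cat(sprintf("  intercept %.3f; bl %.3f; con %.3f; conn %.3f; bl:conn %.3f; con:conn %.3f\n",
              object@beta0, object@betaBlCover, object@betaConCover,
              object@betaConn, object@betaBlConn, object@betaConConn))
  cat(sprintf("  spatial sd %.2f (range %g cells, AR1 rho %.2f)\n",
              object@spatialSd, object@spatialRange, object@rhoT))
})

setMethod("show", "SpeciesModelResult", function(object) {
  cat("SpeciesModelResult:", object@speciesId, "/", object@schemeId,
      "variant", object@variant, "backend", object@backend,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  if (object@converged) print(object@summary, row.names = FALSE)
})

setMethod("show", "MetaResult", function(object) {
  cat("MetaResult for coefficient:", object@coefficient,
      if (object@converged) "(converged)" else "(check convergence)", "\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "PredictionSurface", function(object) {
  g <- object@grid
  cat("PredictionSurface:", nrow(g), "grid points,",
      sum(g$in_envelope), "inside the observed envelope\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat("ModelSpec: variant", object@variant, "| climate",
      object@useClimate, "| phenology", object@usePhenology,
      "| spatial", object@useSpatial, "\n")
})
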