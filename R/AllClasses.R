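#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal bdiag crossprod t solve chol
NULL

.PERIODS <- c("P1", "P2")
.CLIMATE_VARS <- c("gdd5", "tcold", "tseas", "precip", "soilm")
.COVARIATE_VARS <- c("bl_cover", "con_cover", "conn", .CLIMATE_VARS)

#' LandscapeRaster: binary woodland presence on a fine grid
#'
#' Holds one binary presence/absence matrix per woodland class
#' (broadleaf, conifer) for a single time period. A pixel can belong to
#' at most one class; both layers share shape, resolution and origin.
#'
#' @slot broadleaf binary matrix (1 = broadleaf woodland pixel).
#' @slot conifer binary matrix (1 = coniferous woodland pixel).
#' @slot fineRes pixel edge length in metres (default 25).
#' @slot origin x/y coordinates of the lower-left corner, metres.
#' @slot period period label, \code{"P1"} or \code{"P2"}.
#' @exportClass LandscapeRaster
setClass("LandscapeRaster",
  representation(broadleaf = "matrix", conifer = "matrix",
                 fineRes = "numeric", origin = "numeric",
                 period = "character"),
  prototype(fineRes = 25, origin = c(0, 0), period = "P1"))

setValidity("LandscapeRaster", function(object) {
  msg <- character()
  b <- object@broadleaf; k <- object@conifer
  if (!identical(dim(b), dim(k)))
    msg <- c(msg, "broadleaf and conifer layers must share shape")
  if (!all(b %in% c(0, 1)) || !all(k %in% c(0, 1)))
    msg <- c(msg, "layers must be strictly binary")
  if (identical(dim(b), dim(k)) && any(b == 1 & k == 1))
    msg <- c(msg, "a pixel may be woodland in at most one class")
  if (length(object@fineRes) != 1 || object@fineRes <= 0)
    msg <- c(msg, "fineRes must be a single positive number")
  if (!(object@period %in% .PERIODS))
    msg <- c(msg, "period must be 'P1' or 'P2'")
  if (length(msg)) msg else TRUE
})

#' ClimateStack: smooth climate surfaces on the coarse analysis grid
#'
#' Five climate surfaces (growing degree days, coldest-month
#' temperature, temperature seasonality, annual precipitation, soil
#' moisture) for one period, all on the coarse grid.
#'
#' @slot layers named list of numeric matrices, one per variable.
#' @slot period period label.
#' @exportClass ClimateStack
setClass("ClimateStack",
  representation(layers = "list", period = "character"),
  prototype(period = "P1"))

setValidity("ClimateStack", function(object) {
  msg <- character()
  if (!all(.CLIMATE_VARS %in% names(object@layers)))
    msg <- c(msg, paste("layers must be named:",
                        paste(.CLIMATE_VARS, collapse = ", ")))
  dims <- unique(lapply(object@layers, dim))
  if (length(dims) > 1)
    msg <- c(msg, "all surfaces must share the coarse-grid shape")
  if (!all(vapply(object@layers, function(m) all(is.finite(m)), TRUE)))
    msg <- c(msg, "all surfaces must be finite")
  if (!(object@period %in% .PERIODS))
    msg <- c(msg, "period must be 'P1' or 'P2'")
  if (length(msg)) msg else TRUE
})

#' ResistanceSurface: per-pixel resistance with woodland source mask
#'
#' @slot resistance numeric matrix of strictly positive resistances.
#' @slot sourceMask logical matrix, TRUE for woodland (source) pixels.
#' @slot fineRes pixel edge length, metres.
#' @exportClass ResistanceSurface
setClass("ResistanceSurface",
  representation(resistance = "matrix", sourceMask = "matrix",
                 fineRes = "numeric"))

setValidity("ResistanceSurface", function(object) {
  msg <- character()
  if (!identical(dim(object@resistance), dim(object@sourceMask)))
    msg <- c(msg, "resistance and sourceMask must share shape")
  if (any(!is.finite(object@resistance)) || any(object@resistance <= 0))
    msg <- c(msg, "resistances must be strictly positive and finite")
  if (!is.logical(object@sourceMask))
    msg <- c(msg, "sourceMask must be logical")
  if (length(msg)) msg else TRUE
})

#' CurrentMap: cumulative current flow from the moving-window circuit model
#'
#' @slot current numeric matrix of non-negative cumulative current.
#' @slot radiusM moving-window radius in metres.
#' @slot blockSize target-subsampling block size (1 = every woodland
#'   pixel is a target).
#' @slot fineRes pixel edge length, metres.
#' @exportClass CurrentMap
setClass("CurrentMap",
  representation(current = "matrix", radiusM = "numeric",
                 blockSize = "numeric", fineRes = "numeric"))

setValidity("CurrentMap", function(object) {
  msg <- character()
  if (any(object@current < -1e-12))
    msg <- c(msg, "cumulative current must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CovariateGrid: coarse-grid covariates for the occurrence models
#'
#' One row per (cell, period): class cover proportions, connectivity
#' (median current within the cell) and the five climate values.
#' Standardisation parameters are stored once the grid has been
#' standardised so model effects can be mapped back to natural units.
#'
#' @slot data data.frame with columns cell, row, col, period and the
#'   covariate columns.
#' @slot coarseRes coarse cell edge length, metres.
#' @slot dims integer c(nrow, ncol) of the coarse grid.
#' @slot standardisation named list of per-variable list(mean, sd);
#'   empty while the grid holds natural units.
#' @exportClass CovariateGrid
setClass("CovariateGrid",
  representation(data = "data.frame", coarseRes = "numeric",
                 dims = "integer", standardisation = "list"),
  prototype(standardisation = list()))

setValidity("CovariateGrid", function(object) {
  msg <- character()
  need <- c("cell", "row", "col", "period", .COVARIATE_VARS)
  if (!all(need %in% names(object@data)))
    msg <- c(msg, paste("data must contain columns:",
                        paste(need, collapse = ", ")))
  if (length(object@standardisation) == 0 &&
      all(c("bl_cover", "con_cover") %in% names(object@data))) {
    pr <- c(object@data$bl_cover, object@data$con_cover)
    if (length(pr) && (min(pr) < -1e-9 || max(pr) > 1 + 1e-9))
      msg <- c(msg, "cover proportions must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' TruthParams: generating parameters for the synthetic record model
#'
#' Houses every parameter of the generative occurrence/detection model:
#' logit-scale fixed effects per standardised covariate unit,
#' list-length (effort) contrasts, optional non-linear climate response
#' functions and phenology curve, the spatial-field variance/range and
#' the AR(1) correlation linking the two period realisations.
#'
#' @slot beta0 intercept (logit scale).
#' @slot betaBlCover,betaConCover,betaConn,betaBlConn,betaConConn
#'   fixed-effect coefficients per standardised unit.
#' @slot betaBlCover2 quadratic broadleaf-cover coefficient.
#' @slot listLength named numeric, contrasts for short (2-3 species)
#'   and long (4+) visits relative to single-species visits.
#' @slot climateFuns named list of functions of the standardised
#'   climate value, contributions to the logit.
#' @slot phenologyFun function of week-of-year (1-52), logit offset.
#' @slot spatialSd marginal SD of the latent spatial field.
#' @slot spatialRange spatial correlation range, coarse cells.
#' @slot rhoT AR(1) correlation of the field between periods, in (-1, 1).
#' @slot periodEffect additive logit shift for period P2.
#' @exportClass TruthParams
setClass("TruthParams",
  representation(beta0 = "numeric", betaBlCover = "numeric",
                 betaConCover = "numeric", betaConn = "numeric",
                 betaBlConn = "numeric", betaConConn = "numeric",
                 betaBlCover2 = "numeric", listLength = "numeric",
                 climateFuns = "list", phenologyFun = "function",
                 spatialSd = "numeric", spatialRange = "numeric",
                 rhoT = "numeric", periodEffect = "numeric"))

setValidity("TruthParams", function(object) {
  msg <- character()
  if (object@rhoT <= -1 || object@rhoT >= 1)
    msg <- c(msg, "rhoT must lie in (-1, 1)")
  if (object@spatialSd < 0 || object@spatialRange <= 0)
    msg <- c(msg, "spatialSd must be >= 0 and spatialRange > 0")
  if (!all(c("short", "long") %in% names(object@listLength)))
    msg <- c(msg, "listLength must be named c(short=, long=)")
  if (length(msg)) msg else TRUE
})

#' SpeciesModelResult: posterior summaries for one species' model
#'
#' @slot speciesId,schemeId identifiers.
#' @slot variant model variant label.
#' @slot backend inference backend used.
#' @slot converged logical convergence flag; non-converged results
#'   carry an empty summary.
#' @slot summary data.frame with columns effect, mean, sd, q2.5, q97.5.
#' @slot nVisits number of visit rows the model used.
#' @exportClass SpeciesModelResult
setClass("SpeciesModelResult",
  representation(speciesId = "character", schemeId = "character",
                 variant = "character", backend = "character",
                 converged = "logical", summary = "data.frame",
                 nVisits = "integer"))

setValidity("SpeciesModelResult", function(object) {
  msg <- character()
  s <- object@summary
  if (!object@converged && nrow(s) > 0)
    msg <- c(msg, "non-converged results must carry no summaries")
  if (nrow(s) > 0) {
    if (!all(c("effect", "mean", "sd", "q2.5", "q97.5") %in% names(s)))
      msg <- c(msg, "summary must have effect, mean, sd, q2.5, q97.5")
    else if (any(s$`q2.5` > s$`q97.5`))
      msg <- c(msg, "quantile bounds must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' MetaResult: pooled effect and heterogeneity from the meta-analysis
#'
#' @slot coefficient name of the pooled coefficient.
#' @slot summary data.frame rows mu, tau_species, tau_scheme with
#'   posterior mean, median, sd and 95\% interval.
#' @slot schemeSummary per-scheme posterior means of mu + scheme effect.
#' @slot speciesShrinkage posterior means of the species-level true
#'   effects (theta).
#' @slot draws named list of posterior draws (mu, tau_species,
#'   tau_scheme), chains concatenated.
#' @slot rhat split-Rhat per monitored parameter.
#' @slot converged TRUE when all split-Rhat < 1.01.
#' @slot priors prior settings used.
#' @exportClass MetaResult
setClass("MetaResult",
  representation(coefficient = "character", summary = "data.frame",
                 schemeSummary = "data.frame",
                 speciesShrinkage = "data.frame", draws = "list",
                 rhat = "numeric", converged = "logical",
                 priors = "list"))

setValidity("MetaResult", function(object) {
  msg <- character()
  s <- object@summary
  if (nrow(s)) {
    tauRows <- grepl("^tau", s$parameter)
    if (any(s$`q2.5`[tauRows] < -1e-12))
      msg <- c(msg, "heterogeneity SDs must be non-negative")
    if (any(s$`q2.5` > s$`q97.5`))
      msg <- c(msg, "interval bounds must be ordered")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionSurface: occurrence predictions over cover x connectivity
#'
#' @slot grid data.frame with standardised and natural coordinates,
#'   posterior mean probability, 95\% interval and envelope mask.
#'   Points outside the observed envelope carry NA predictions.
#' @slot baselineLogit logit of occurrence at mean covariates.
#' @exportClass PredictionSurface
setClass("PredictionSurface",
  representation(grid = "data.frame", baselineLogit = "numeric"))

setValidity("PredictionSurface", function(object) {
  g <- object@grid
  msg <- character()
  inside <- g$in_envelope
  p <- g$mean[inside]
  if (length(p) && (any(p <= 0) || any(p >= 1)))
    msg <- c(msg, "probabilities must lie in (0, 1)")
  if (any(!inside & !is.na(g$mean)))
    msg <- c(msg, "masked points must carry no predictions")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: structure and priors of the per-species occurrence model
#'
#' @slot variant one of "main", "no_cover", "under30", "quadratic".
#' @slot useClimate,usePhenology,useSpatial switch the latent
#'   components on/off.
#' @slot nBinsClimate number of equal-count bins per climate smooth.
#' @slot priorSdFixed SD of the Gaussian prior on fixed effects
#'   (Inf = flat).
#' @slot smoothSd innovation SD of the second-order random walks.
#' @slot fieldSd marginal SD of the spatial field.
#' @slot fieldRange field correlation range, coarse cells.
#' @slot rhoT AR(1) correlation between the period field realisations.
#' @slot fieldNodesPer field-lattice spacing, coarse cells per node.
#' @slot estimateHyper empirical-Bayes optimisation of the latent
#'   component SDs (otherwise they are fixed at the slots above).
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(variant = "character", useClimate = "logical",
                 usePhenology = "logical", useSpatial = "logical",
                 nBinsClimate = "integer", priorSdFixed = "numeric",
                 smoothSd = "numeric", fieldSd = "numeric",
                 fieldRange = "numeric", rhoT = "numeric",
                 fieldNodesPer = "integer", estimateHyper = "logical"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!(object@variant %in% c("main", "no_cover", "under30", "quadratic")))
    msg <- c(msg, "variant must be main, no_cover, under30 or quadratic")
  if (object@rhoT <= -1 || object@rhoT >= 1)
    msg <- c(msg, "rhoT must lie in (-1, 1)")
  if (object@fieldSd <= 0 || object@fieldRange <= 0 || object@smoothSd <= 0)
    msg <- c(msg, "component SDs and range must be positive")
  if (length(msg)) msg else TRUE
})
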