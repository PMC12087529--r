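## Cover x connectivity prediction surfaces from pooled effect draws.
##
## Per grid point and posterior draw d the linear predictor is
## baseline + bCover_d * x_cov + bConn_d * x_conn + bInt_d * x_cov *
## x_conn, mapped through the inverse logit; predictions are
## summarised across draws and masked to the observed covariate
## envelope (per cover bin, the observed connectivity range), since
## the interaction extrapolates without bound outside it. Conifer
## terms are held at zero (their standardised mean).

#' Observed cover-connectivity envelope of a covariate grid
#'
#' Bins standardised broadleaf cover and records the observed
#' connectivity range per bin; a (cover, connectivity) point is inside
#' the envelope when its cover bin is populated and its connectivity
#' lies within that bin's range.
#'
#' @param covGrid a standardised \code{CovariateGrid}.
#' @param nBins number of equal-width cover bins.
#' @return list(breaks, minConn, maxConn) usable by
#'   \code{\link{predictSurface}}.
#' @export
computeEnvelope <- function(covGrid, nBins = 20) {
  stopifnot(is(covGrid, "CovariateGrid"))
  if (length(standardisation(covGrid)) == 0)
    stop("envelope is computed on the standardised grid")
  dat <- covariates(covGrid)
  breaks <- seq(min(dat$bl_cover), max(dat$bl_cover),
                length.out = nBins + 1)
  bin <- findInterval(dat$bl_cover, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  minConn <- rep(NA_real_, nBins); maxConn <- rep(NA_real_, nBins)
  for (b in unique(bin)) {
    minConn[b] <- min(dat$conn[bin == b])
    maxConn[b] <- max(dat$conn[bin == b])
  }
  list(breaks = breaks, minConn = minConn, maxConn = maxConn)
}

.inEnvelope <- function(envelope, cover, conn) {
  if (is.null(envelope)) return(rep(TRUE, length(cover)))
  nBins <- length(envelope$minConn)
  bin <- findInterval(cover, envelope$breaks, rightmost.closed = TRUE)
  ok <- bin >= 1 & bin <= nBins
  ok[ok] <- !is.na(envelope$minConn[bin[ok]]) &
    conn[ok] >= envelope$minConn[bin[ok]] &
    conn[ok] <= envelope$maxConn[bin[ok]]
  ok
}

#' Predict occurrence over the cover x connectivity plane
#'
#' @param drawsCover,drawsConn,drawsInteraction posterior draws of the
#'   pooled broadleaf-cover, connectivity and interaction effects
#'   (equal lengths; paired by index within each model, independent
#'   across models).
#' @param covGrid optional standardised \code{CovariateGrid}; supplies
#'   the default grid extent, the envelope and natural units.
#' @param coverValues,connValues standardised grid coordinates
#'   (defaults: 41 points spanning the observed range, or [-2, 2]).
#' @param envelope envelope from \code{\link{computeEnvelope}};
#'   computed from \code{covGrid} when omitted, or \code{NA} to
#'   disable masking.
#' @param baselineLogit occurrence logit at mean covariates
#'   (predictions are relative; 0 gives probability 0.5 there).
#' @return a \code{\link{PredictionSurface-class}}.
#' @export
predictSurface <- function(drawsCover, drawsConn, drawsInteraction,
                           covGrid = NULL, coverValues = NULL,
                           connValues = NULL, envelope = NULL,
                           baselineLogit = 0) {
  nd <- length(drawsCover)
  if (length(drawsConn) != nd || length(drawsInteraction) != nd)
    stop("draw vectors must have equal length")
  if (nd == 0) stop("empty draw vectors")
  std <- NULL
  if (!is.null(covGrid)) {
    std <- standardisation(covGrid)
    dat <- covariates(covGrid)
    if (is.null(coverValues))
      coverValues <- seq(min(dat$bl_cover), max(dat$bl_cover),
                         length.out = 41)
    if (is.null(connValues))
      connValues <- seq(min(dat$conn), max(dat$conn), length.out = 41)
    if (is.null(envelope)) envelope <- computeEnvelope(covGrid)
  }
  if (is.null(coverValues)) coverValues <- seq(-2, 2, length.out = 41)
  if (is.null(connValues)) connValues <- seq(-2, 2, length.out = 41)
  if (isTRUE(is.na(envelope))) envelope <- NULL

  grid <- expand.grid(cover_std = coverValues, conn_std = connValues,
                      KEEP.OUT.ATTRS = FALSE)
  inside <- .inEnvelope(envelope, grid$cover_std, grid$conn_std)
  if (!any(inside)) stop("empty envelope: no grid point is observable")

  grid$mean <- NA_real_; grid$`q2.5` <- NA_real_; grid$`q97.5` <- NA_real_
  idx <- which(inside)
  for (i in idx) {
    eta <- baselineLogit + drawsCover * grid$cover_std[i] +
      drawsConn * grid$conn_std[i] +
      drawsInteraction * grid$cover_std[i] * grid$conn_std[i]
    pr <- invlogit(eta)
    grid$mean[i] <- mean(pr)
    qs <- stats::quantile(pr, c(0.025, 0.975), names = FALSE)
    grid$`q2.5`[i] <- qs[1]; grid$`q97.5`[i] <- qs[2]
  }
  grid$in_envelope <- inside
  if (!is.null(std) && length(std)) {
    grid$cover_nat <- toNatural(std, "bl_cover", grid$cover_std)
    grid$conn_nat <- toNatural(std, "conn", grid$conn_std)
  } else {
    grid$cover_nat <- NA_real_; grid$conn_nat <- NA_real_
  }
  new("PredictionSurface", grid = grid, baselineLogit = baselineLogit)
}

#' Marginal connectivity slope at given cover values
#'
#' The slope of occurrence (logit scale) in connectivity at cover x is
#' bConn + bInt * x: positive at low cover and, with a negative
#' interaction, decreasing — and eventually negative — as cover grows.
#'
#' @param connResult,interactionResult \code{MetaResult} objects for
#'   the connectivity and interaction coefficients.
#' @param coverValues cover values in natural proportion units.
#' @param std standardisation parameters of the covariate grid (needed
#'   to express cover in standardised units).
#' @return data.frame per cover value: posterior mean, 95\% interval
#'   and the posterior probability the slope is positive.
#' @export
connectivityEffectAtCover <- function(connResult, interactionResult,
                                      coverValues, std) {
  stopifnot(is(connResult, "MetaResult"),
            is(interactionResult, "MetaResult"))
  if (is.null(std[["bl_cover"]]))
    stop("missing standardisation parameters for bl_cover")
  dConn <- metaDraws(connResult)$mu
  dInt <- metaDraws(interactionResult)$mu
  nd <- min(length(dConn), length(dInt))
  dConn <- dConn[seq_len(nd)]; dInt <- dInt[seq_len(nd)]
  out <- lapply(coverValues, function(cv) {
    x <- toStandard(std, "bl_cover", cv)
    slope <- dConn + dInt * x
    data.frame(cover = cv, cover_std = x, mean = mean(slope),
               `q2.5` = stats::quantile(slope, 0.025, names = FALSE),
               `q97.5` = stats::quantile(slope, 0.975, names = FALSE),
               prob_positive = mean(slope > 0), check.names = FALSE)
  })
  do.call(rbind, out)
}
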