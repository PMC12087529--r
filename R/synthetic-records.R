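## Synthetic multi-scheme occurrence records.
##
## The generative model mirrors the occurrence model that is later
## fitted: per-visit detection of each species is Bernoulli with
## probability inverse-logit of (intercept + cover/connectivity fixed
## effects + climate responses + phenology + spatial field + period
## effect + list-length effort contrast). The recording process and
## occurrence are not separated in the fitted model (effort enters
## through list length only), so the generator's split between a
## latent per-visit effort class and species occurrence is a modelling
## choice, not something the study data can identify.

#' Default non-linear climate response functions
#'
#' Gentle non-linear responses on the logit scale for two of the five
#' climate variables (saturating response to growing degree days, an
#' inverted-U in coldest-month temperature); the remaining variables
#' have no effect. Inputs are standardised climate values.
#'
#' @return named list of functions, one per climate variable.
#' @export
defaultClimateFuns <- function() {
  list(gdd5   = function(x) 0.3 * tanh(x),
       tcold  = function(x) 0.2 - 0.2 * x^2,
       tseas  = function(x) rep(0, length(x)),
       precip = function(x) rep(0, length(x)),
       soilm  = function(x) rep(0, length(x)))
}

#' Default unimodal phenology curve
#'
#' Cosine bump peaking in midsummer (week 26), amplitude 0.8 on the
#' logit scale.
#'
#' @return function of week-of-year (1-52).
#' @export
defaultPhenology <- function() {
  function(week) 0.8 * cos(2 * pi * (week - 26) / 52)
}

#' Construct generating-model parameters
#'
#' Bundles every parameter of the synthetic occurrence/detection model.
#' Fixed-effect defaults are the pooled effect sizes used as generating
#' truths in the package's recovery experiments; list-length contrasts
#' and the spatial-field defaults are documented choices (see the
#' methods vignette).
#'
#' @param beta0 intercept, logit scale.
#' @param betaBlCover,betaConCover,betaConn,betaBlConn,betaConConn
#'   fixed effects per standardised covariate unit.
#' @param betaBlCover2 quadratic broadleaf-cover coefficient.
#' @param listLength named contrasts for short (2-3) and long (4+)
#'   visits relative to single-species visits.
#' @param climateFuns named list of climate response functions.
#' @param phenologyFun phenology curve over weeks 1-52.
#' @param spatialSd,spatialRange marginal SD and range (coarse cells)
#'   of the latent spatial field (\code{spatialSd = 0} disables it).
#' @param rhoT AR(1) correlation of the field between periods.
#' @param periodEffect additive logit shift in period P2.
#' @return a \code{\link{TruthParams-class}} object.
#' @export
truthParams <- function(beta0 = -1, betaBlCover = 0.246,
                        betaConCover = 0, betaConn = 0.148,
                        betaBlConn = -0.050, betaConConn = 0,
                        betaBlCover2 = 0,
                        listLength = c(short = 0.7, long = 1.4),
                        climateFuns = defaultClimateFuns(),
                        phenologyFun = defaultPhenology(),
                        spatialSd = 0.4, spatialRange = 8, rhoT = 0.8,
                        periodEffect = 0) {
  new("TruthParams", beta0 = beta0, betaBlCover = betaBlCover,
      betaConCover = betaConCover, betaConn = betaConn,
      betaBlConn = betaBlConn, betaConConn = betaConConn,
      betaBlCover2 = betaBlCover2, listLength = listLength,
      climateFuns = climateFuns, phenologyFun = phenologyFun,
      spatialSd = spatialSd, spatialRange = spatialRange, rhoT = rhoT,
      periodEffect = periodEffect)
}

#' Closed-form visit-level detection probability
#'
#' Evaluates the generating model's detection probability for visit
#' rows: inverse-logit of the full linear predictor. Used both by the
#' record generator and as the analytic reference that empirical
#' detection frequencies must converge to.
#'
#' @param truth a \code{TruthParams}.
#' @param rows data.frame with columns \code{bl_cover}, \code{con_cover},
#'   \code{conn}, the climate variables, \code{week},
#'   \code{list_length_class} (single/short/long), \code{period}, and
#'   optionally \code{field} (spatial-field value, default 0).
#' @return numeric vector of probabilities.
#' @export
visitProbability <- function(truth, rows) {
  stopifnot(is(truth, "TruthParams"))
  eta <- truth@beta0 +
    truth@betaBlCover * rows$bl_cover +
    truth@betaConCover * rows$con_cover +
    truth@betaConn * rows$conn +
    truth@betaBlConn * rows$bl_cover * rows$conn +
    truth@betaConConn * rows$con_cover * rows$conn +
    truth@betaBlCover2 * rows$bl_cover^2
  for (v in names(truth@climateFuns))
    if (v %in% names(rows)) eta <- eta + truth@climateFuns[[v]](rows[[v]])
  if ("week" %in% names(rows)) eta <- eta + truth@phenologyFun(rows$week)
  ll <- as.character(rows$list_length_class)
  eta <- eta + ifelse(ll == "short", truth@listLength["short"],
              ifelse(ll == "long", truth@listLength["long"], 0))
  if ("period" %in% names(rows))
    eta <- eta + ifelse(rows$period == "P2", truth@periodEffect, 0)
  if ("field" %in% names(rows)) eta <- eta + rows$field
  unname(invlogit(eta))
}

## Simulate the latent spatial field for one species: a smooth
## unit-variance field scaled to spatialSd for P1, AR(1)-linked
## innovation for P2. Returns list(P1=, P2=) matrices on the coarse grid.
simulateSpeciesField <- function(truth, nr, nc) {
  if (truth@spatialSd <= 0)
    return(list(P1 = matrix(0, nr, nc), P2 = matrix(0, nr, nc)))
  sigma <- truth@spatialRange / 2  # smoothing length ~ half the range
  u1 <- smoothField(nr, nc, sigma, sd = truth@spatialSd)
  innov <- smoothField(nr, nc, sigma, sd = truth@spatialSd)
  u2 <- truth@rhoT * u1 + sqrt(1 - truth@rhoT^2) * innov
  list(P1 = u1, P2 = u2)
}

#' Generate multi-scheme citizen-science occurrence records
#'
#' Simulates visits (random cell, date, recording scheme and a latent
#' effort class) and, for every species in the visiting scheme's pool,
#' a Bernoulli detection with the closed-form probability of
#' \code{\link{visitProbability}}. Only detections are emitted, as in
#' unstructured recording-scheme data; non-detections are reconstructed
#' downstream by the visit builder.
#'
#' @param truths named list of \code{TruthParams}, one per species id.
#' @param schemes data.frame with columns \code{species_id},
#'   \code{scheme_id}; schemes own disjoint species pools.
#' @param covariates a standardised \code{CovariateGrid}.
#' @param nVisits number of visits to simulate.
#' @param p1Window,p2Window date windows (character length 2,
#'   ISO dates) of the two periods.
#' @param periodWeights sampling weights of the two periods (the later
#'   period default reflects the growth of recording effort).
#' @param effortProbs probabilities of the latent effort classes.
#' @param impreciseFrac fraction of emitted records given a coarse
#'   (2000 m) location precision so record filtering has something to
#'   remove; default 0.
#' @param seed optional RNG seed.
#' @return list with elements \code{records} (data.frame species_id,
#'   scheme_id, cell_id, date, precision_m), \code{visits} (the latent
#'   visit table with covariates and effort class) and \code{fields}
#'   (per-species spatial-field realisations).
#' @export
genRecords <- function(truths, schemes, covariates, nVisits,
                       p1Window = c("1990-01-01", "1999-12-31"),
                       p2Window = c("2015-01-01", "2021-12-31"),
                       periodWeights = c(P1 = 1, P2 = 2),
                       effortProbs = c(single = 0.4, short = 0.35,
                                       long = 0.25),
                       impreciseFrac = 0, seed = NULL) {
  stopifnot(is(covariates, "CovariateGrid"))
  if (length(standardisation(covariates)) == 0)
    stop("covariates must be standardised before generating records")
  if (!all(schemes$species_id %in% names(truths)))
    stop("every species in 'schemes' needs an entry in 'truths'")
  if (nrow(schemes) == 0) stop("empty species pool")
  if (anyDuplicated(schemes$species_id))
    stop("schemes must own disjoint species pools")
  if (!is.null(seed)) set.seed(seed)

  cov <- covariates(covariates)
  dims <- covariates@dims
  schemeIds <- unique(schemes$scheme_id)
  windows <- list(P1 = as.Date(p1Window), P2 = as.Date(p2Window))

  periods <- sample(names(periodWeights), nVisits, replace = TRUE,
                    prob = periodWeights)
  rowsByPeriod <- split(seq_len(nrow(cov)), cov$period)
  visitCovRow <- integer(nVisits)
  for (p in unique(periods)) {
    sel <- which(periods == p)
    visitCovRow[sel] <- sample(rowsByPeriod[[p]], length(sel),
                               replace = TRUE)
  }
  dates <- as.Date(vapply(seq_len(nVisits), function(i) {
    w <- windows[[periods[i]]]
    as.numeric(sample(seq(w[1], w[2], by = "day"), 1))
  }, 0), origin = "1970-01-01")

  visits <- cov[visitCovRow, , drop = FALSE]
  visits$visit <- seq_len(nVisits)
  visits$date <- dates
  visits$week <- isoWeek52(dates)
  visits$scheme_id <- sample(schemeIds, nVisits, replace = TRUE)
  visits$list_length_class <- factor(
    sample(names(effortProbs), nVisits, replace = TRUE,
           prob = effortProbs),
    levels = c("single", "short", "long"))
  rownames(visits) <- NULL

  fields <- lapply(truths, simulateSpeciesField, nr = dims[1],
                   nc = dims[2])

  recs <- vector("list", nrow(schemes))
  for (k in seq_len(nrow(schemes))) {
    sp <- schemes$species_id[k]
    sc <- schemes$scheme_id[k]
    sel <- visits$scheme_id == sc
    if (!any(sel)) next
    vv <- visits[sel, , drop = FALSE]
    fld <- fields[[sp]]
    idx <- cbind(vv$row + 1L, vv$col + 1L)
    vv$field <- ifelse(vv$period == "P2", fld$P2[idx], fld$P1[idx])
    p <- visitProbability(truths[[sp]], vv)
    hit <- stats::runif(nrow(vv)) < p
    if (!any(hit)) next
    recs[[k]] <- data.frame(
      species_id = sp, scheme_id = sc,
      cell_id = vv$cell[hit], date = vv$date[hit],
      precision_m = 1000, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(records))
    records <- data.frame(species_id = character(), scheme_id = character(),
                          cell_id = integer(), date = as.Date(character()),
                          precision_m = numeric())
  rownames(records) <- NULL
  if (impreciseFrac > 0 && nrow(records) > 0) {
    k <- round(impreciseFrac * nrow(records))
    if (k > 0) records$precision_m[sample(nrow(records), k)] <- 2000
  }
  list(records = records, visits = visits, fields = fields)
}
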