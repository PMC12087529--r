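## Synthetic landscape and climate generation.
##
## Landscapes are generated by thresholding Gaussian-smoothed white
## noise at the cover-target quantile: the smoothing length controls
## spatial clustering independently of total cover, which is exactly
## the cover-versus-fragmentation contrast the downstream analysis
## needs. Broadleaf is generated first; the conifer layer is drawn
## independently and conflicts are resolved in favour of broadleaf
## (classes are treated as disjoint throughout).

#' Generate a binary two-class woodland landscape
#'
#' Thresholds independent Gaussian-smoothed white-noise fields so that
#' each class occupies (to pixel rounding) its target cover fraction.
#' Larger \code{clustering} produces more aggregated (less fragmented)
#' woodland at the same cover.
#'
#' @param nrow,ncol fine-grid shape (pixels).
#' @param coverBroadleaf,coverConifer target cover proportions; their
#'   sum must not exceed 1.
#' @param clustering Gaussian smoothing length in pixels (> 0);
#'   controls spatial autocorrelation of the woodland pattern.
#' @param fineRes pixel edge length, metres.
#' @param origin lower-left corner coordinates, metres.
#' @param period period label ("P1" or "P2").
#' @param seed optional RNG seed; the same seed reproduces the
#'   landscape bit-identically.
#' @return a \code{\link{LandscapeRaster-class}} object.
#' @examples
#' ls1 <- genLandscape(60, 60, coverBroadleaf = 0.1, coverConifer = 0.05,
#'                     clustering = 3, seed = 1)
#' coverFraction(ls1, "broadleaf")
#' @export
genLandscape <- function(nrow, ncol, coverBroadleaf = 0.10,
                         coverConifer = 0.05, clustering = 3,
                         fineRes = 25, origin = c(0, 0), period = "P1",
                         seed = NULL) {
  if (nrow <= 0 || ncol <= 0)
    stop("landscape shape must be positive")
  if (coverBroadleaf < 0 || coverConifer < 0 ||
      coverBroadleaf > 1 || coverConifer > 1)
    stop("cover targets must lie in [0, 1]")
  if (coverBroadleaf + coverConifer > 1)
    stop("cover targets must sum to at most 1")
  if (clustering <= 0)
    stop("clustering must be positive")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow * ncol
  zb <- gaussSmooth(matrix(stats::rnorm(n), nrow, ncol), clustering)
  zc <- gaussSmooth(matrix(stats::rnorm(n), nrow, ncol), clustering)

  bl <- matrix(0, nrow, ncol)
  kB <- round(coverBroadleaf * n)
  if (kB > 0) bl[order(zb, decreasing = TRUE)[seq_len(kB)]] <- 1

  con <- matrix(0, nrow, ncol)
  kC <- min(round(coverConifer * n), n - kB)
  if (kC > 0) {
    cand <- which(bl == 0)
    con[cand[order(zc[cand], decreasing = TRUE)[seq_len(kC)]]] <- 1
  }

  new("LandscapeRaster", broadleaf = bl, conifer = con,
      fineRes = fineRes, origin = as.numeric(origin), period = period)
}

#' Evolve a landscape into the second period
#'
#' Produces the period-2 layer by first removing a fraction of each
#' class's woodland pixels (loss) and then converting a fraction of the
#' matrix pixels 8-adjacent to remaining woodland of that class (gain).
#' Matrix pixels adjacent to both classes convert to broadleaf.
#'
#' @param x a period-1 \code{LandscapeRaster}.
#' @param gainFrac fraction of woodland-adjacent matrix pixels that
#'   become woodland, in [0, 1].
#' @param lossFrac fraction of woodland pixels removed, in [0, 1].
#' @param seed optional RNG seed.
#' @return a \code{LandscapeRaster} labelled period "P2".
#' @export
evolveLandscape <- function(x, gainFrac = 0.05, lossFrac = 0.02,
                            seed = NULL) {
  stopifnot(is(x, "LandscapeRaster"))
  if (gainFrac < 0 || gainFrac > 1 || lossFrac < 0 || lossFrac > 1)
    stop("gainFrac and lossFrac must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  bl <- x@broadleaf; con <- x@conifer

  dropFrac <- function(m, frac) {
    idx <- which(m == 1)
    k <- round(frac * length(idx))
    if (k > 0) m[sample(idx, k)] <- 0
    m
  }
  bl <- dropFrac(bl, lossFrac)
  con <- dropFrac(con, lossFrac)

  if (gainFrac > 0) {
    adjBl <- which(neighbourCount(bl) > 0 & bl == 0 & con == 0)
    adjCon <- which(neighbourCount(con) > 0 & bl == 0 & con == 0)
    adjCon <- setdiff(adjCon, adjBl)  # broadleaf takes precedence
    kB <- round(gainFrac * length(adjBl))
    kC <- round(gainFrac * length(adjCon))
    if (kB > 0) bl[sample(adjBl, kB)] <- 1
    if (kC > 0) con[sample(adjCon, kC)] <- 1
  }

  new("LandscapeRaster", broadleaf = bl, conifer = con,
      fineRes = x@fineRes, origin = x@origin, period = "P2")
}

## Number of 8-neighbours equal to 1, zero-padded borders.
neighbourCount <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out + p[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

#' Generate smooth correlated climate surfaces
#'
#' Five spatially smooth surfaces on the coarse grid (growing degree
#' days, coldest-month temperature, temperature seasonality, annual
#' precipitation, soil moisture), each a Gaussian-smoothed white-noise
#' field. A shared component induces configurable inter-variable
#' correlation. Units are arbitrary: downstream modelling standardises
#' every covariate anyway.
#'
#' @param nrow,ncol coarse-grid shape.
#' @param smoothness Gaussian smoothing length in coarse cells;
#'   larger values give flatter surfaces.
#' @param interCor correlation induced between variables via a shared
#'   smooth component, in [0, 1).
#' @param period period label.
#' @param seed optional RNG seed.
#' @return a \code{\link{ClimateStack-class}} object.
#' @export
genClimate <- function(nrow, ncol, smoothness = 5, interCor = 0.3,
                       period = "P1", seed = NULL) {
  if (nrow <= 0 || ncol <= 0) stop("coarse shape must be positive")
  if (interCor < 0 || interCor >= 1) stop("interCor must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  common <- gaussSmooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                        smoothness)
  layers <- lapply(.CLIMATE_VARS, function(v) {
    own <- gaussSmooth(matrix(stats::rnorm(nrow * ncol), nrow, ncol),
                       smoothness)
    sqrt(interCor) * common + sqrt(1 - interCor) * own
  })
  names(layers) <- .CLIMATE_VARS
  new("ClimateStack", layers = layers, period = period)
}

#' Perturb a climate stack into a second period
#'
#' Adds independent smooth noise of relative magnitude \code{sd} to
#' each surface, emulating between-period climate change while keeping
#' the spatial pattern strongly correlated across periods.
#'
#' @param x a \code{ClimateStack}.
#' @param sd magnitude of the perturbation relative to each surface's
#'   spatial SD.
#' @param smoothness smoothing length of the perturbation field.
#' @param period new period label.
#' @param seed optional RNG seed.
#' @return a perturbed \code{ClimateStack}.
#' @export
perturbClimate <- function(x, sd = 0.3, smoothness = 5, period = "P2",
                           seed = NULL) {
  stopifnot(is(x, "ClimateStack"))
  if (!is.null(seed)) set.seed(seed)
  layers <- lapply(x@layers, function(m) {
    s <- stats::sd(as.vector(m))
    m + smoothField(nrow(m), ncol(m), smoothness, sd = sd * max(s, 1e-12))
  })
  new("ClimateStack", layers = layers, period = period)
}
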