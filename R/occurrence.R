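## Per-species Bayesian spatio-temporal occurrence model.
##
## Bernoulli-logit likelihood over visit rows. Linear predictor:
## intercept + cover/connectivity fixed effects (variant-dependent) +
## list-length contrasts + RW2 smooths of the five climate covariates +
## a cyclic RW2 phenology term over weeks + a Gaussian Markov random
## field on a coarse lattice whose two period realisations are linked
## by an AR(1) correlation. All latent components are Gaussian, so the
## joint posterior mode plus Gaussian (Laplace) curvature gives the
## posterior summaries; an independence-Metropolis MCMC backend using
## the Laplace fit as proposal is available as a cross-check.

.FIXED_EFFECTS <- c("intercept", "bl_cover", "con_cover", "connectivity",
                    "bl_cover:connectivity", "con_cover:connectivity",
                    "bl_cover_sq", "ll_short", "ll_long")

#' Construct a model specification
#'
#' @param variant model variant: \code{"main"} (all fixed effects),
#'   \code{"no_cover"} (cover and interaction terms removed, used for
#'   the cover-quartile analyses), \code{"under30"} (main formula on a
#'   spatial subset) or \code{"quadratic"} (adds a broadleaf-cover
#'   quadratic term).
#' @param useClimate,usePhenology,useSpatial enable the RW2 climate
#'   smooths, cyclic phenology term and spatial field.
#' @param nBinsClimate equal-count bins per climate smooth.
#' @param priorSdFixed SD of the zero-mean Gaussian prior on fixed
#'   effects; \code{Inf} gives a flat prior.
#' @param smoothSd innovation SD of the second-order random walks.
#' @param fieldSd,fieldRange marginal SD and correlation range (coarse
#'   cells) of the spatial field.
#' @param rhoT AR(1) correlation linking the two period fields.
#' @param fieldNodesPer coarse cells per field-lattice node.
#' @param estimateHyper optimise the latent SDs by empirical Bayes
#'   (maximising the Laplace-approximate marginal posterior) instead of
#'   fixing them at the values above.
#' @return a \code{\link{ModelSpec-class}} object.
#' @export
modelSpec <- function(variant = c("main", "no_cover", "under30",
                                  "quadratic"),
                      useClimate = TRUE, usePhenology = TRUE,
                      useSpatial = TRUE, nBinsClimate = 20L,
                      priorSdFixed = 1, smoothSd = 0.3, fieldSd = 0.5,
                      fieldRange = 10, rhoT = 0.8, fieldNodesPer = 5L,
                      estimateHyper = FALSE) {
  new("ModelSpec", variant = match.arg(variant),
      useClimate = useClimate, usePhenology = usePhenology,
      useSpatial = useSpatial, nBinsClimate = as.integer(nBinsClimate),
      priorSdFixed = priorSdFixed, smoothSd = smoothSd,
      fieldSd = fieldSd, fieldRange = fieldRange, rhoT = rhoT,
      fieldNodesPer = as.integer(fieldNodesPer),
      estimateHyper = estimateHyper)
}

#' Inference configuration
#'
#' @param backend \code{"laplace"} (default) or \code{"mcmc"}
#'   (independence Metropolis around the Laplace fit; cross-check use).
#' @param maxIter,tol Newton iteration cap and gradient tolerance.
#' @param mcmcIter,mcmcChains,mcmcWarmup sampler settings.
#' @return a list of class \code{inferenceConfig}.
#' @export
inferenceConfig <- function(backend = c("laplace", "mcmc"),
                            maxIter = 100L, tol = 1e-9,
                            mcmcIter = 2000L, mcmcChains = 4L,
                            mcmcWarmup = 200L) {
  structure(list(backend = match.arg(backend),
                 maxIter = as.integer(maxIter), tol = tol,
                 mcmcIter = as.integer(mcmcIter),
                 mcmcChains = as.integer(mcmcChains),
                 mcmcWarmup = as.integer(mcmcWarmup)),
            class = "inferenceConfig")
}

## Second-difference penalty structure matrix R = D'D for an RW2 over
## n ordered bins; cyclic wraps the differences around.
rw2Structure <- function(n, cyclic = FALSE) {
  if (cyclic) {
    D <- matrix(0, n, n)
    for (i in seq_len(n)) {
      D[i, i] <- -2
      D[i, (i %% n) + 1L] <- 1
      D[i, ((i - 2L) %% n) + 1L] <- 1
    }
  } else {
    if (n < 3) stop("RW2 needs at least 3 bins")
    D <- matrix(0, n - 2L, n)
    for (i in seq_len(n - 2L)) D[i, i + 0:2] <- c(1, -2, 1)
  }
  crossprod(D)
}

## Precision of one RW2 block: innovation precision times the structure
## plus a soft sum-to-zero constraint and a tiny ridge that makes the
## (otherwise intrinsic) prior proper.
rw2Precision <- function(n, cyclic, smoothSd) {
  R <- rw2Structure(n, cyclic)
  tau <- 1 / smoothSd^2
  Q <- tau * R + 1e-6 * diag(n) + (100 / n) * matrix(1, n, n)
  Matrix::Matrix(Q, sparse = TRUE)
}

## Equal-count binning of a covariate. Returns bin index per value and
## the number of bins actually formed (ties can merge bins).
equalCountBins <- function(x, nBins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nBins + 1),
                               type = 7))
  if (length(br) < 3) return(NULL)
  idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(idx = idx, n = length(br) - 1L)
}

## Spatial GMRF precision: Whittle-Matern-like lattice operator
## Q0 = kappa^4 I + 2 kappa^2 L + L^2 on an mr x mc 4-neighbour
## lattice, normalised so the mean marginal variance is fieldSd^2,
## then AR(1)-coupled across the two periods.
fieldPrecision <- function(mr, mc, fieldSd, rangeNodes, rhoT) {
  m <- mr * mc
  idx <- matrix(seq_len(m), mr, mc)
  ii <- jj <- integer(0)
  addE <- function(a, b) { ii <<- c(ii, a); jj <<- c(jj, b) }
  if (mr > 1) addE(as.vector(idx[-mr, ]), as.vector(idx[-1, ]))
  if (mc > 1) addE(as.vector(idx[, -mc]), as.vector(idx[, -1]))
  deg <- tabulate(c(ii, jj), m)
  L <- Matrix::sparseMatrix(i = c(ii, jj, seq_len(m)),
                            j = c(jj, ii, seq_len(m)),
                            x = c(rep(-1, 2 * length(ii)), deg),
                            dims = c(m, m))
  kappa <- sqrt(8) / max(rangeNodes, 0.5)
  Q0 <- kappa^4 * Matrix::Diagonal(m) + 2 * kappa^2 * L + L %*% L
  vbar <- mean(Matrix::diag(Matrix::solve(Q0)))
  Qs <- (vbar / fieldSd^2) * Q0
  A2 <- matrix(c(1, -rhoT, -rhoT, 1), 2) / (1 - rhoT^2)
  list(Q = Matrix::kronecker(A2, Qs), m = m, mr = mr, mc = mc)
}

## Assemble fixed-effect design matrix for a variant.
fixedDesign <- function(dat, variant) {
  X <- cbind(intercept = rep(1, nrow(dat)))
  if (variant != "no_cover") {
    X <- cbind(X, bl_cover = dat$bl_cover, con_cover = dat$con_cover)
  }
  X <- cbind(X, connectivity = dat$conn)
  if (variant != "no_cover") {
    X <- cbind(X, `bl_cover:connectivity` = dat$bl_cover * dat$conn,
               `con_cover:connectivity` = dat$con_cover * dat$conn)
    if (variant == "quadratic")
      X <- cbind(X, bl_cover_sq = dat$bl_cover^2)
  }
  ll <- as.character(dat$list_length_class)
  X <- cbind(X, ll_short = as.numeric(ll == "short"),
             ll_long = as.numeric(ll == "long"))
  ## drop empty effort levels (and any degenerate column) so the
  ## Hessian stays full rank under flat priors
  keep <- c(TRUE, vapply(2:ncol(X), function(j)
    stats::sd(X[, j]) > 0, TRUE))
  X[, keep, drop = FALSE]
}

## Build latent blocks: list of (A sparse map, Q precision, label).
latentBlocks <- function(dat, spec, gridDims, fieldNodesPer) {
  blocks <- list()
  n <- nrow(dat)
  if (spec@useClimate) {
    for (v in .CLIMATE_VARS) {
      b <- equalCountBins(dat[[v]], spec@nBinsClimate)
      if (is.null(b)) next
      A <- Matrix::sparseMatrix(i = seq_len(n), j = b$idx, x = 1,
                                dims = c(n, b$n))
      blocks[[paste0("clim_", v)]] <-
        list(A = A, Q = rw2Precision(b$n, FALSE, spec@smoothSd),
             type = "smooth")
    }
  }
  if (spec@usePhenology) {
    A <- Matrix::sparseMatrix(i = seq_len(n), j = dat$week, x = 1,
                              dims = c(n, 52))
    blocks[["phenology"]] <-
      list(A = A, Q = rw2Precision(52, TRUE, spec@smoothSd),
           type = "smooth")
  }
  if (spec@useSpatial) {
    mr <- max(1L, ceiling(gridDims[1] / fieldNodesPer))
    mc <- max(1L, ceiling(gridDims[2] / fieldNodesPer))
    if (mr * mc >= 4) {
      fp <- fieldPrecision(mr, mc, spec@fieldSd,
                           spec@fieldRange / fieldNodesPer, spec@rhoT)
      nodeRow <- pmin(dat$row %/% fieldNodesPer, mr - 1L)
      nodeCol <- pmin(dat$col %/% fieldNodesPer, mc - 1L)
      node <- nodeRow * mc + nodeCol + 1L
      node <- node + ifelse(dat$period == "P2", fp$m, 0L)
      A <- Matrix::sparseMatrix(i = seq_len(n), j = node, x = 1,
                                dims = c(n, 2L * fp$m))
      blocks[["spatial"]] <- list(A = A, Q = fp$Q, type = "field")
    }
  }
  blocks
}

## Newton optimisation of the joint log posterior (beta, u). Returns
## mode, joint Hessian at the mode, convergence flag.
newtonJoint <- function(z, M, P, maxIter, tol) {
  d <- ncol(M)
  theta <- rep(0, d)
  obj <- function(th) {
    eta <- as.numeric(M %*% th)
    -sum(z * eta - log1p(exp(eta))) + 0.5 * sum(th * as.numeric(P %*% th))
  }
  f <- obj(theta)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(M %*% theta)
    p <- invlogit(eta)
    w <- pmax(p * (1 - p), 1e-12)
    grad <- as.numeric(Matrix::crossprod(M, z - p)) -
      as.numeric(P %*% theta)
    H <- Matrix::crossprod(M * sqrt(w)) + P
    step <- tryCatch(as.numeric(Matrix::solve(H, grad)),
                     error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      f2 <- obj(theta + alpha * step)
      if (is.finite(f2) && f2 <= f + 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    theta <- theta + alpha * step
    f <- obj(theta)
    if (max(abs(grad)) < tol || max(abs(alpha * step)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  eta <- as.numeric(M %*% theta)
  p <- invlogit(eta)
  w <- pmax(p * (1 - p), 1e-12)
  H <- Matrix::crossprod(M * sqrt(w)) + P
  pd <- tryCatch({ Matrix::chol(H); TRUE }, error = function(e) FALSE)
  list(theta = theta, H = H, converged = converged && pd,
       logpost = -f)
}

## Laplace-approximate log marginal posterior of the latent log-SDs,
## used by the empirical-Bayes option. Exponential(1) priors on the
## component SDs penalise complexity.
ebObjective <- function(logSds, z, M, p, blocks, priorPrecFixed,
                        maxIter, tol) {
  sds <- exp(logSds)
  Qs <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    sc <- if (blocks[[k]]$type == "smooth") sds[1] else sds[2]
    base <- blocks[[k]]$Qunit
    Qs[[k]] <- base / sc^2
  }
  P <- Matrix::bdiag(c(list(Matrix::Diagonal(p, priorPrecFixed)), Qs))
  fit <- newtonJoint(z, M, P, maxIter, tol)
  if (!fit$converged) return(1e10)
  ldP <- sum(vapply(Qs, function(Q)
    2 * sum(log(Matrix::diag(Matrix::chol(Q)))), 0))
  ldH <- 2 * sum(log(Matrix::diag(Matrix::chol(fit$H))))
  -(fit$logpost + 0.5 * ldP - 0.5 * ldH - sum(sds) + sum(logSds))
}

#' Fit the per-species occurrence model
#'
#' @param detections detection/non-detection table from
#'   \code{\link{detectionMatrix}} (needs at least one 1 and one 0;
#'   degenerate responses return a non-converged result).
#' @param covGrid a standardised \code{CovariateGrid}.
#' @param spec a \code{\link{modelSpec}}.
#' @param config an \code{\link{inferenceConfig}}.
#' @param speciesId,schemeId identifiers stored on the result.
#' @param seed RNG seed (MCMC backend only).
#' @return a \code{\link{SpeciesModelResult-class}} with posterior
#'   mean, SD and 95\% interval per fixed effect.
#' @export
fitSpeciesModel <- function(detections, covGrid, spec = modelSpec(),
                            config = inferenceConfig(),
                            speciesId = "sp", schemeId = "scheme",
                            seed = NULL) {
  stopifnot(is(covGrid, "CovariateGrid"), is(spec, "ModelSpec"))
  if (length(standardisation(covGrid)) == 0)
    stop("covariates must be standardised")
  notConverged <- function() new("SpeciesModelResult",
    speciesId = speciesId, schemeId = schemeId, variant = spec@variant,
    backend = config$backend, converged = FALSE,
    summary = data.frame(), nVisits = nrow(detections))
  if (length(unique(detections$response)) < 2) return(notConverged())

  cov <- covariates(covGrid)
  key <- paste(cov$cell, cov$period)
  dat <- cbind(detections,
               cov[match(paste(detections$cell_id, detections$period),
                         key),
                   c("row", "col", "bl_cover", "con_cover", "conn",
                     .CLIMATE_VARS)])
  if (anyNA(dat$bl_cover))
    stop("some visits reference cells missing from the covariate grid")

  z <- dat$response
  X <- fixedDesign(dat, spec@variant)
  p <- ncol(X)
  blocks <- latentBlocks(dat, spec, covGrid@dims, spec@fieldNodesPer)

  priorPrecFixed <- if (is.infinite(spec@priorSdFixed)) 0 else
    1 / spec@priorSdFixed^2

  if (spec@estimateHyper && length(blocks)) {
    for (k in seq_along(blocks)) {
      sd0 <- if (blocks[[k]]$type == "smooth") spec@smoothSd else
        spec@fieldSd
      blocks[[k]]$Qunit <- blocks[[k]]$Q * sd0^2
    }
    M <- cbind(Matrix::Matrix(X, sparse = TRUE),
               do.call(cbind, lapply(blocks, `[[`, "A")))
    opt <- stats::optim(log(c(spec@smoothSd, spec@fieldSd)),
                        ebObjective, z = z, M = M, p = p,
                        blocks = blocks,
                        priorPrecFixed = priorPrecFixed,
                        maxIter = config$maxIter, tol = config$tol,
                        method = "Nelder-Mead",
                        control = list(maxit = 40))
    sds <- exp(opt$par)
    for (k in seq_along(blocks)) {
      sc <- if (blocks[[k]]$type == "smooth") sds[1] else sds[2]
      blocks[[k]]$Q <- blocks[[k]]$Qunit / sc^2
    }
  }

  M <- if (length(blocks))
    cbind(Matrix::Matrix(X, sparse = TRUE),
          do.call(cbind, lapply(blocks, `[[`, "A")))
  else Matrix::Matrix(X, sparse = TRUE)
  P <- if (length(blocks))
    Matrix::bdiag(c(list(Matrix::Diagonal(p, priorPrecFixed)),
                    lapply(blocks, `[[`, "Q")))
  else Matrix::Diagonal(p, priorPrecFixed)

  fit <- newtonJoint(z, M, P, config$maxIter, config$tol)
  if (!fit$converged) return(notConverged())

  if (config$backend == "laplace") {
    E <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                              dims = c(ncol(M), p))
    V <- as.matrix(Matrix::solve(fit$H, E))[seq_len(p), , drop = FALSE]
    est <- fit$theta[seq_len(p)]
    sds <- sqrt(pmax(diag(V), 0))
    summ <- data.frame(effect = colnames(X), mean = est, sd = sds,
                       `q2.5` = est + stats::qnorm(0.025) * sds,
                       `q97.5` = est + stats::qnorm(0.975) * sds,
                       check.names = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    summ <- mcmcFixedSummary(z, M, P, fit, p, colnames(X), config)
    if (is.null(summ)) return(notConverged())
  }
  rownames(summ) <- NULL
  new("SpeciesModelResult", speciesId = speciesId, schemeId = schemeId,
      variant = spec@variant, backend = config$backend,
      converged = TRUE, summary = summ, nVisits = nrow(detections))
}

## Independence-Metropolis sampler with the Laplace fit as proposal.
## Returns NULL when split-Rhat of any fixed effect exceeds 1.05.
mcmcFixedSummary <- function(z, M, P, fit, p, effectNames, config) {
  d <- ncol(M)
  Hs <- as.matrix(fit$H)
  R <- chol(Hs + 1e-10 * diag(d))  # upper: H = R'R, cov = R^-1 R^-T
  logq <- function(th) {
    dd <- th - fit$theta
    -0.5 * sum((R %*% dd)^2)
  }
  logpost <- function(th) {
    eta <- as.numeric(M %*% th)
    sum(z * eta - log1p(exp(eta))) -
      0.5 * sum(th * as.numeric(P %*% th))
  }
  nIter <- config$mcmcIter; nCh <- config$mcmcChains
  keep <- array(NA_real_, c(nIter, nCh, p))
  for (ch in seq_len(nCh)) {
    th <- fit$theta
    lp <- logpost(th); lq <- logq(th)
    for (it in seq_len(nIter + config$mcmcWarmup)) {
      prop <- fit$theta + backsolve(R, stats::rnorm(d))
      lpP <- logpost(prop); lqP <- logq(prop)
      if (log(stats::runif(1)) < (lpP - lp) - (lqP - lq)) {
        th <- prop; lp <- lpP; lq <- lqP
      }
      if (it > config$mcmcWarmup)
        keep[it - config$mcmcWarmup, ch, ] <- th[seq_len(p)]
    }
  }
  rhats <- vapply(seq_len(p), function(j) splitRhat(keep[, , j]), 0)
  if (any(rhats > 1.05)) return(NULL)
  draws <- apply(keep, 3, as.vector)
  data.frame(effect = effectNames,
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             `q2.5` = apply(draws, 2, stats::quantile, 0.025),
             `q97.5` = apply(draws, 2, stats::quantile, 0.975),
             check.names = FALSE)
}

#' Classify a species' woodland association
#'
#' Applies the credible-interval rules to the main-variant fixed
#' effects: broadleaf-associated when the broadleaf-cover 95\% interval
#' lies entirely above zero, coniferous-associated likewise for conifer
#' cover, \code{"both"} when both hold, \code{"avoiding"} when both
#' upper bounds are below zero, otherwise \code{"none"}.
#'
#' @param result a converged main-variant \code{SpeciesModelResult}.
#' @return one of \code{"broadleaf"}, \code{"coniferous"},
#'   \code{"both"}, \code{"avoiding"}, \code{"none"}.
#' @export
classifyAssociation <- function(result) {
  stopifnot(is(result, "SpeciesModelResult"))
  if (!result@converged)
    stop("cannot classify a non-converged model result")
  if (result@variant != "main")
    stop("association is classified from the main variant")
  s <- result@summary
  getRow <- function(eff) s[s$effect == eff, , drop = FALSE]
  bl <- getRow("bl_cover"); con <- getRow("con_cover")
  if (nrow(bl) == 0 || nrow(con) == 0)
    stop("summary lacks the cover effects")
  blPos <- bl$`q2.5` > 0
  conPos <- con$`q2.5` > 0
  blNeg <- bl$`q97.5` < 0
  conNeg <- con$`q97.5` < 0
  if (blPos && conPos) return("both")
  if (blPos) return("broadleaf")
  if (conPos) return("coniferous")
  if (blNeg && conNeg) return("avoiding")
  "none"
}

#' Spatially subset landscapes and detections
#'
#' Retains only visits whose (cell, period) satisfies a broadleaf-cover
#' rule, either a fixed threshold (\code{type = "under_cover"}) or a
#' quartile of the positive-cover distribution (\code{type =
#' "quartile"}; boundaries by linear-interpolation quantiles of the
#' cells with cover > 0, pooled over periods).
#'
#' @param covGrid a \code{CovariateGrid} (standardised or natural; the
#'   rule operates on natural cover proportions).
#' @param detections a detection table (or NULL to subset the grid only).
#' @param rule list(type = "under_cover", threshold =) or
#'   list(type = "quartile", q = 1..4).
#' @return list(covGrid =, detections =) subset to the rule.
#' @export
subsetLandscapes <- function(covGrid, detections, rule) {
  stopifnot(is(covGrid, "CovariateGrid"))
  dat <- covariates(covGrid)
  std <- standardisation(covGrid)
  coverNat <- if (length(std)) toNatural(std, "bl_cover", dat$bl_cover)
              else dat$bl_cover
  if (rule$type == "under_cover") {
    keep <- coverNat < rule$threshold
  } else if (rule$type == "quartile") {
    pos <- coverNat[coverNat > 0]
    if (length(pos) < 4) stop("too few positive-cover landscapes")
    qs <- stats::quantile(pos, probs = c(0, 0.25, 0.5, 0.75, 1),
                          type = 7)
    lo <- qs[rule$q]; hi <- qs[rule$q + 1]
    keep <- coverNat > 0 & coverNat <= hi &
      (if (rule$q == 1) coverNat >= lo else coverNat > lo)
  } else stop("unknown subset rule type")
  if (!any(keep)) stop("subset rule yields an empty landscape set")
  sub <- dat[keep, , drop = FALSE]
  g <- new("CovariateGrid", data = sub, coarseRes = covGrid@coarseRes,
           dims = covGrid@dims, standardisation = std)
  if (!is.null(detections)) {
    ok <- paste(detections$cell_id, detections$period) %in%
      paste(sub$cell, sub$period)
    if (!any(ok)) stop("subset rule yields an empty detection set")
    detections <- detections[ok, , drop = FALSE]
  }
  list(covGrid = g, detections = detections)
}

#' Quartile boundaries of the positive broadleaf-cover distribution
#'
#' @param covGrid a \code{CovariateGrid}.
#' @return the 0/25/50/75/100\% quantiles of positive natural cover.
#' @export
coverQuartiles <- function(covGrid) {
  dat <- covariates(covGrid)
  std <- standardisation(covGrid)
  coverNat <- if (length(std)) toNatural(std, "bl_cover", dat$bl_cover)
              else dat$bl_cover
  pos <- coverNat[coverNat > 0]
  stats::quantile(pos, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7)
}
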