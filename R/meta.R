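## Measurement-error random-effects meta-analysis.
##
## Model: y_i ~ Normal(theta_i, s_i^2), theta_i = mu + a_scheme(i) + b_i,
## a_s ~ Normal(0, tau_scheme^2), b_i ~ Normal(0, tau_species^2), with
## the per-species standard error s_i known. The species effect is
## identifiable despite one observation per species exactly because
## s_i is known. Inference is a blocked Gibbs sampler: mu and the
## scheme effects are updated from their Gaussian conditionals with the
## species effects analytically marginalised (y_i - a_s ~ N(mu,
## s_i^2 + tau_species^2)); the two heterogeneity SDs are updated by
## slice sampling on the log scale, tau_scheme against the fully
## marginal likelihood (both random-effect layers integrated out via
## the compound-symmetry within-scheme covariance). Marginalisation
## removes the funnel-shaped dependence that plain Gibbs mixes poorly
## over.

## Univariate slice sampler (stepping out, Neal 2003) on the log scale.
sliceSample <- function(x0, logf, w = 1, maxSteps = 50) {
  fx <- logf(x0)
  if (!is.finite(fx)) stop("slice sampler started at zero density")
  y <- fx + log(stats::runif(1))
  L <- x0 - stats::runif(1) * w
  R <- L + w
  k <- maxSteps
  while (k > 0 && logf(L) > y) { L <- L - w; k <- k - 1 }
  k <- maxSteps
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## Marginal log-likelihood of y given mu and the two taus, both
## random-effect layers integrated out. Within-scheme covariance is
## diag(s^2 + tauB^2) + tauA^2 * 11'; Sherman-Morrison gives the
## determinant and quadratic form in O(n_s).
marginalLoglik <- function(r, v, schemeRows, tauA) {
  ll <- 0
  for (rows in schemeRows) {
    vi <- v[rows]; ri <- r[rows]
    si <- sum(1 / vi)
    den <- 1 + tauA^2 * si
    quad <- sum(ri^2 / vi) - tauA^2 * sum(ri / vi)^2 / den
    ll <- ll - 0.5 * (sum(log(vi)) + log(den) + quad)
  }
  ll
}

#' Pool species effects with a measurement-error meta-analysis
#'
#' Fits the two-level random-effects model with known per-species
#' standard errors by MCMC (blocked Gibbs with slice updates for the
#' heterogeneity SDs; half-Normal priors on the SDs, a wide Normal
#' prior on the pooled mean). With a single recording scheme the
#' between-scheme SD is fixed at zero with a warning.
#'
#' @param effects data.frame with columns \code{species_id},
#'   \code{scheme_id}, \code{estimate} (logit scale) and \code{se}
#'   (> 0).
#' @param coefficient label stored on the result.
#' @param nIter kept iterations per chain.
#' @param nChains number of chains.
#' @param warmup discarded iterations per chain.
#' @param muPriorSd SD of the Normal prior on the pooled mean.
#' @param tauPriorScale scale of the half-Normal priors on the SDs.
#' @param seed RNG seed.
#' @return a \code{\link{MetaResult-class}}; convergence requires
#'   split-Rhat < 1.01 for the pooled mean and both SDs.
#' @export
fitMeta <- function(effects, coefficient = "connectivity",
                    nIter = 2500L, nChains = 4L, warmup = 500L,
                    muPriorSd = 10, tauPriorScale = 1, seed = NULL) {
  need <- c("species_id", "scheme_id", "estimate", "se")
  if (!all(need %in% names(effects)))
    stop("effects needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(effects$se)) || any(effects$se <= 0))
    stop("all standard errors must be finite and positive")
  if (anyDuplicated(paste(effects$species_id, coefficient)))
    stop("one row per species per coefficient")
  if (!is.null(seed)) set.seed(seed)

  y <- effects$estimate
  s2 <- effects$se^2
  n <- length(y)
  scheme <- factor(effects$scheme_id)
  S <- nlevels(scheme)
  schemeRows <- split(seq_len(n), scheme)
  singleScheme <- S < 2
  if (singleScheme)
    warning("single recording scheme: tau_scheme fixed at 0")

  half <- function(tau) stats::dnorm(tau, 0, tauPriorScale, log = TRUE)

  runChain <- function() {
    mu <- mean(y); tauB <- max(stats::sd(y) / 2, 0.05); tauA <- 0.05
    a <- numeric(S)
    out <- matrix(NA_real_, nIter, 3 + S)
    thetaSum <- numeric(n)
    for (it in seq_len(warmup + nIter)) {
      v <- s2 + tauB^2
      ## mu | a, tauB (species effects marginal)
      prec <- sum(1 / v) + 1 / muPriorSd^2
      mn <- sum((y - a[scheme]) / v) / prec
      mu <- stats::rnorm(1, mn, sqrt(1 / prec))
      ## tauA | mu, tauB (both layers marginal), then a | the rest
      r <- y - mu
      if (!singleScheme) {
        lfA <- function(lt) {
          tau <- exp(lt)
          marginalLoglik(r, v, schemeRows, tau) + half(tau) + lt
        }
        tauA <- exp(sliceSample(log(max(tauA, 1e-4)), lfA))
        for (sIdx in seq_len(S)) {
          rows <- schemeRows[[sIdx]]
          precS <- 1 / tauA^2 + sum(1 / v[rows])
          mnS <- sum(r[rows] / v[rows]) / precS
          a[sIdx] <- stats::rnorm(1, mnS, sqrt(1 / precS))
        }
      }
      ## tauB | mu, a (species effects marginal)
      r2 <- y - mu - a[scheme]
      lfB <- function(lt) {
        tau <- exp(lt)
        vv <- s2 + tau^2
        -0.5 * sum(log(vv) + r2^2 / vv) + half(tau) + lt
      }
      tauB <- exp(sliceSample(log(max(tauB, 1e-4)), lfB))
      if (it > warmup) {
        out[it - warmup, ] <- c(mu, tauB, tauA, mu + a)
        precB <- 1 / s2 + 1 / tauB^2
        bHat <- (r2 / s2) / precB
        thetaSum <- thetaSum + mu + a[scheme] +
          stats::rnorm(n, bHat, sqrt(1 / precB))
      }
    }
    list(draws = out, thetaMean = thetaSum / nIter)
  }

  chains <- lapply(seq_len(nChains), function(i) runChain())
  drawArr <- lapply(chains, `[[`, "draws")
  monNames <- c("mu", "tau_species", "tau_scheme")
  rhat <- vapply(1:3, function(j)
    splitRhat(sapply(drawArr, function(m) m[, j])), 0)
  names(rhat) <- monNames
  if (singleScheme) rhat["tau_scheme"] <- 1
  all_ <- do.call(rbind, drawArr)

  summarise <- function(x, name) data.frame(
    parameter = name, mean = mean(x), median = stats::median(x),
    sd = stats::sd(x),
    `q2.5` = unname(stats::quantile(x, 0.025)),
    `q97.5` = unname(stats::quantile(x, 0.975)),
    check.names = FALSE)
  summ <- rbind(summarise(all_[, 1], "mu"),
                summarise(all_[, 2], "tau_species"),
                summarise(all_[, 3], "tau_scheme"))
  schemeSumm <- do.call(rbind, lapply(seq_len(S), function(j)
    summarise(all_[, 3 + j], levels(scheme)[j])))
  shrink <- data.frame(
    species_id = effects$species_id,
    theta_mean = rowMeans(sapply(chains, `[[`, "thetaMean")),
    stringsAsFactors = FALSE)

  new("MetaResult", coefficient = coefficient, summary = summ,
      schemeSummary = schemeSumm, speciesShrinkage = shrink,
      draws = list(mu = all_[, 1], tau_species = all_[, 2],
                   tau_scheme = all_[, 3]),
      rhat = rhat, converged = all(rhat < 1.01),
      priors = list(muPriorSd = muPriorSd,
                    tauPriorScale = tauPriorScale))
}

#' Tabulate the direction of species-level effects
#'
#' Counts species whose 95\% credible interval for a coefficient lies
#' entirely above zero (positive), entirely below (negative), or
#' crosses zero (neither), with percentages.
#'
#' @param results list of converged main-variant
#'   \code{SpeciesModelResult} objects.
#' @param coefficient effect name, e.g. \code{"connectivity"}.
#' @return data.frame with direction, count and percentage rows.
#' @export
tabulateDirections <- function(results, coefficient = "connectivity") {
  results <- Filter(function(r) isConverged(r) && r@variant == "main",
                    results)
  if (length(results) == 0) stop("no converged main-variant results")
  dir1 <- vapply(results, function(r) {
    s <- r@summary
    row <- s[s$effect == coefficient, , drop = FALSE]
    if (nrow(row) == 0) return(NA_character_)
    if (row$`q2.5` > 0) "positive"
    else if (row$`q97.5` < 0) "negative"
    else "neither"
  }, "")
  dir1 <- dir1[!is.na(dir1)]
  if (length(dir1) == 0) stop("coefficient absent from all results")
  counts <- table(factor(dir1, levels = c("positive", "negative",
                                          "neither")))
  data.frame(direction = names(counts),
             count = as.integer(counts),
             percent = 100 * as.integer(counts) / length(dir1),
             stringsAsFactors = FALSE)
}
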