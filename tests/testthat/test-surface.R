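test_that("zero draws and baseline give a flat surface at one half", {
  d <- rep(0, 100)
  s <- predictSurface(d, d, d, coverValues = seq(-1, 1, 0.5),
                      connValues = seq(-1, 1, 0.5), envelope = NA,
                      baselineLogit = 0)
  g <- surfaceGrid(s)
  expect_true(all(abs(g$mean - 0.5) < 1e-12))
  expect_true(all(g$`q97.5` - g$`q2.5` < 1e-12))
})

test_that("the marginal connectivity slope flips sign at cover 2.96 SD", {
  ## with pooled means 0.148 and -0.050 the slope 0.148 - 0.050 x
  ## crosses zero at x = 2.96
  mkMeta <- function(mu) methods::new(
    "MetaResult", coefficient = "x",
    summary = data.frame(parameter = "mu", mean = mu, median = mu,
                         sd = 0, `q2.5` = mu, `q97.5` = mu,
                         check.names = FALSE),
    schemeSummary = data.frame(), speciesShrinkage = data.frame(),
    draws = list(mu = rep(mu, 50), tau_species = rep(0, 50),
                 tau_scheme = rep(0, 50)),
    rhat = c(mu = 1), converged = TRUE, priors = list())
  std <- list(bl_cover = list(mean = 0, sd = 1))
  flip <- 0.148 / 0.050
  tab <- connectivityEffectAtCover(mkMeta(0.148), mkMeta(-0.050),
                                   coverValues = c(flip - 0.01, flip,
                                                   flip + 0.01),
                                   std = std)
  expect_gt(tab$mean[1], 0)
  expect_lt(abs(tab$mean[2]), 1e-12)
  expect_lt(tab$mean[3], 0)
  expect_equal(flip, 2.96)
})

test_that("slope in cover is constant without, decreasing with, interaction", {
  mkMeta <- function(draws) methods::new(
    "MetaResult", coefficient = "x",
    summary = data.frame(parameter = "mu", mean = mean(draws),
                         median = mean(draws), sd = stats::sd(draws),
                         `q2.5` = min(draws), `q97.5` = max(draws),
                         check.names = FALSE),
    schemeSummary = data.frame(), speciesShrinkage = data.frame(),
    draws = list(mu = draws, tau_species = draws * 0,
                 tau_scheme = draws * 0),
    rhat = c(mu = 1), converged = TRUE, priors = list())
  std <- list(bl_cover = list(mean = 0.1, sd = 0.05))
  set.seed(3)
  conn <- rnorm(200, 0.148, 0.02)
  tab0 <- connectivityEffectAtCover(mkMeta(conn), mkMeta(rep(0, 200)),
                                    c(0.05, 0.15, 0.30), std)
  expect_lt(diff(range(tab0$mean)), 1e-12)
  tabN <- connectivityEffectAtCover(mkMeta(conn),
                                    mkMeta(rnorm(200, -0.05, 0.005)),
                                    c(0.05, 0.15, 0.30), std)
  expect_true(all(diff(tabN$mean) < 0))
})

test_that("probability ranking matches linear-predictor ranking", {
  set.seed(9)
  dC <- rnorm(300, 0.25, 0.05); dK <- rnorm(300, 0.15, 0.05)
  dI <- rnorm(300, -0.05, 0.02)
  s <- predictSurface(dC, dK, dI, coverValues = seq(-2, 2, 1),
                      connValues = seq(-2, 2, 1), envelope = NA)
  g <- surfaceGrid(s)
  eta <- mean(dC) * g$cover_std + mean(dK) * g$conn_std +
    mean(dI) * g$cover_std * g$conn_std
  ## not identical (mean of probs vs prob of means) but same ordering
  ## up to Monte-Carlo noise at well separated points
  o1 <- order(eta); o2 <- order(g$mean)
  expect_gt(stats::cor(rank(eta), rank(g$mean)), 0.99)
  expect_true(all(g$`q97.5` >= g$`q2.5`))
})

test_that("the surface is symmetric under exchanging the two axes", {
  set.seed(10)
  A <- rnorm(100, 0.3, 0.01); B <- rnorm(100, 0.1, 0.01)
  I <- rnorm(100, -0.04, 0.01)
  vals <- seq(-1, 1, 0.5)
  s1 <- surfaceGrid(predictSurface(A, B, I, coverValues = vals,
                                   connValues = vals, envelope = NA))
  s2 <- surfaceGrid(predictSurface(B, A, I, coverValues = vals,
                                   connValues = vals, envelope = NA))
  for (i in seq_len(nrow(s1))) {
    j <- which(abs(s2$cover_std - s1$conn_std[i]) < 1e-12 &
                 abs(s2$conn_std - s1$cover_std[i]) < 1e-12)
    expect_equal(s1$mean[i], s2$mean[j], tolerance = 1e-12)
  }
})

test_that("the envelope masks unobserved cover-connectivity combinations", {
  g <- mkStdGrid(10, 10, seed = 20)
  env <- computeEnvelope(g, nBins = 10)
  s <- predictSurface(rep(0.2, 50), rep(0.1, 50), rep(-0.05, 50),
                      covGrid = g)
  gr <- surfaceGrid(s)
  expect_true(any(!gr$in_envelope))
  expect_true(all(is.na(gr$mean[!gr$in_envelope])))
  expect_true(all(!is.na(gr$mean[gr$in_envelope])))
  ## natural units round-trip
  std <- standardisation(g)
  expect_equal(gr$cover_nat,
               toNatural(std, "bl_cover", gr$cover_std))
})

test_that("mismatched draw lengths are rejected", {
  expect_error(predictSurface(1:5, 1:4, 1:5), "equal length")
})
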