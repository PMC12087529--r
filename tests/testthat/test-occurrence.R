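test_that("with flat priors and no latent terms the fit equals logistic regression", {
  set.seed(71)
  sim <- simDetections(1500, flatTruth(), seed = 72)
  fit <- fitSpeciesModel(sim$det, sim$grid, flatSpec())
  expect_true(isConverged(fit))
  cov <- covariates(sim$grid)
  key <- paste(cov$cell, cov$period)
  dd <- cbind(sim$det,
              cov[match(paste(sim$det$cell_id, sim$det$period), key),
                  c("bl_cover", "con_cover", "conn")])
  g <- stats::glm(response ~ bl_cover + con_cover + conn +
                    bl_cover:conn + con_cover:conn +
                    list_length_class, family = stats::binomial,
                  data = dd)
  nm <- c("(Intercept)", "bl_cover", "con_cover", "conn",
          "bl_cover:conn", "con_cover:conn",
          "list_length_classshort", "list_length_classlong")
  expect_lt(max(abs(effectSummary(fit)$mean - unname(stats::coef(g)[nm]))),
            1e-4)
  ## Laplace SDs agree with the glm curvature too
  expect_lt(max(abs(effectSummary(fit)$sd -
                      unname(summary(g)$coefficients[nm, 2]))), 1e-4)
})

test_that("the generating connectivity effect is recovered at 4000 visits", {
  set.seed(73)
  truth <- flatTruth(beta0 = -1, betaBlCover = 0.246, betaConn = 0.148,
                     betaBlConn = -0.05)
  sim <- simDetections(4000, truth, seed = 74)
  fit <- fitSpeciesModel(sim$det, sim$grid, modelSpec(
    useClimate = FALSE, usePhenology = FALSE, useSpatial = FALSE))
  es <- effectSummary(fit)
  row <- es[es$effect == "connectivity", ]
  expect_lt(abs(row$mean - 0.148), 3 * row$sd)
})

test_that("model variants include and exclude the right effects", {
  set.seed(75)
  sim <- simDetections(800, flatTruth(), seed = 76)
  eff <- function(spec) effectSummary(
    fitSpeciesModel(sim$det, sim$grid, spec))$effect
  noCover <- eff(flatSpec("no_cover"))
  expect_false(any(grepl("cover", noCover)))
  expect_true("connectivity" %in% noCover)
  quad <- eff(flatSpec("quadratic"))
  expect_true("bl_cover_sq" %in% quad)
  expect_false("bl_cover_sq" %in% eff(flatSpec("main")))
})

test_that("degenerate responses come back flagged, not fitted", {
  sim <- simDetections(100, flatTruth(beta0 = 50), seed = 77)
  expect_true(all(sim$det$response == 1))
  fit <- fitSpeciesModel(sim$det, sim$grid, flatSpec())
  expect_false(isConverged(fit))
  expect_equal(nrow(effectSummary(fit)), 0)
})

test_that("latent components fit and the cyclic phenology wraps around", {
  ## structural wrap-around: the penalty couples weeks 1 and 52
  R <- woodflow:::rw2Structure(52, cyclic = TRUE)
  expect_true(R[1, 52] != 0)
  expect_true(R[1, 51] != 0)
  expect_true(all(abs(rowSums(R)) < 1e-10))  # constants unpenalised
  set.seed(78)
  truth <- truthParams(spatialSd = 0)
  sim <- simDetections(1200, truth, seed = 79)
  fit <- fitSpeciesModel(sim$det, sim$grid,
                         modelSpec(useSpatial = FALSE))
  expect_true(isConverged(fit))
  expect_equal(nrow(effectSummary(fit)), 8)
})

test_that("the MCMC backend agrees with the Laplace fit", {
  set.seed(80)
  sim <- simDetections(1200, flatTruth(), seed = 81)
  la <- fitSpeciesModel(sim$det, sim$grid, flatSpec())
  mc <- fitSpeciesModel(sim$det, sim$grid, flatSpec(),
                        inferenceConfig(backend = "mcmc",
                                        mcmcIter = 1500),
                        seed = 82)
  expect_true(isConverged(mc))
  dif <- abs(effectSummary(la)$mean - effectSummary(mc)$mean)
  expect_lt(max(dif / pmax(effectSummary(la)$sd, 1e-6)), 0.3)
})

test_that("association classes follow the credible-interval rules", {
  mkRes <- function(bl, con) {
    s <- data.frame(effect = c("intercept", "bl_cover", "con_cover"),
                    mean = c(0, mean(bl), mean(con)), sd = 1,
                    `q2.5` = c(-1, bl[1], con[1]),
                    `q97.5` = c(1, bl[2], con[2]), check.names = FALSE)
    methods::new("SpeciesModelResult", speciesId = "x", schemeId = "s",
                 variant = "main", backend = "laplace",
                 converged = TRUE, summary = s, nVisits = 10L)
  }
  expect_equal(classifyAssociation(mkRes(c(0.1, 0.4), c(-0.2, 0.1))),
               "broadleaf")
  expect_equal(classifyAssociation(mkRes(c(-0.2, 0.1), c(0.1, 0.3))),
               "coniferous")
  expect_equal(classifyAssociation(mkRes(c(0.1, 0.4), c(0.05, 0.3))),
               "both")
  expect_equal(classifyAssociation(mkRes(c(-0.4, -0.1), c(-0.3, -0.05))),
               "avoiding")
  expect_equal(classifyAssociation(mkRes(c(-0.1, 0.2), c(-0.2, 0.1))),
               "none")
  ## one-sided negatives without the partner stay 'none'
  expect_equal(classifyAssociation(mkRes(c(-0.4, -0.1), c(-0.1, 0.2))),
               "none")
  nc <- methods::new("SpeciesModelResult", speciesId = "x",
                     schemeId = "s", variant = "main",
                     backend = "laplace", converged = FALSE,
                     summary = data.frame(), nVisits = 0L)
  expect_error(classifyAssociation(nc), "non-converged")
})

test_that("landscape subsetting applies thresholds and quartiles", {
  g <- mkStdGrid(8, 8, seed = 83)
  ## quartile boundaries of {1..8}% positive cover
  raw <- covariates(g)
  covNat <- toNatural(standardisation(g), "bl_cover", raw$bl_cover)
  covNat[] <- 0
  covNat[1:8] <- (1:8) / 100
  raw$bl_cover <- toStandard(standardisation(g), "bl_cover", covNat)
  gr <- methods::new("CovariateGrid", data = raw, coarseRes = 1000,
                     dims = g@dims,
                     standardisation = standardisation(g))
  qs <- coverQuartiles(gr)
  expect_equal(unname(qs[2:4]), c(2.75, 4.5, 6.25) / 100)
  ## zero-cover cells are excluded from quartile construction
  sub1 <- subsetLandscapes(gr, NULL, list(type = "quartile", q = 1))
  cn <- toNatural(standardisation(gr), "bl_cover",
                  covariates(sub1$covGrid)$bl_cover)
  expect_true(all(cn > 0))
  ## under-30% threshold on an all-50% grid is empty
  raw2 <- covariates(g)
  raw2$bl_cover <- toStandard(standardisation(g), "bl_cover",
                              rep(0.5, nrow(raw2)))
  gr2 <- methods::new("CovariateGrid", data = raw2, coarseRes = 1000,
                      dims = g@dims,
                      standardisation = standardisation(g))
  expect_error(subsetLandscapes(gr2, NULL,
                                list(type = "under_cover",
                                     threshold = 0.30)), "empty")
})
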