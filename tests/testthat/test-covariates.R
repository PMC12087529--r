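mkCurrent <- function(m, fineRes = 25)
  methods::new("CurrentMap", current = m, radiusM = 100,
               blockSize = 1, fineRes = fineRes)

mkClimateConst <- function(nr, nc, period = "P1") {
  layers <- lapply(seq_along(woodflow:::.CLIMATE_VARS),
                   function(i) matrix(i, nr, nc))
  names(layers) <- woodflow:::.CLIMATE_VARS
  methods::new("ClimateStack", layers = layers, period = period)
}

test_that("aggregation computes cover fractions and the current median", {
  ## 4x4 fine grid, one 4x4 coarse cell with 4 broadleaf pixels
  b <- matrix(0, 4, 4); b[1, 1:4] <- 1
  land <- methods::new("LandscapeRaster", broadleaf = b,
                       conifer = matrix(0, 4, 4), fineRes = 25,
                       origin = c(0, 0), period = "P1")
  cur <- matrix(0, 4, 4); cur[1:4] <- c(0, 0, 1, 3)
  g <- aggregateCovariates(mkCurrent(cur), land, mkClimateConst(1, 1),
                           coarseRes = 100)
  dat <- covariates(g)
  expect_equal(nrow(dat), 1)
  expect_equal(dat$bl_cover, 0.25)
  ## median of 12 zeros and {0,1,3} values: still 0 here
  expect_equal(dat$conn, 0)
  ## an all-woodland cell has cover exactly 1
  landF <- methods::new("LandscapeRaster",
                        broadleaf = matrix(1, 4, 4),
                        conifer = matrix(0, 4, 4), fineRes = 25,
                        origin = c(0, 0), period = "P1")
  gF <- aggregateCovariates(mkCurrent(matrix(2, 4, 4)), landF,
                            mkClimateConst(1, 1), 100)
  expect_equal(covariates(gF)$bl_cover, 1)
})

test_that("the even-count median averages the middle pair", {
  ## one coarse cell of 2x2 pixels with currents {0,0,1,3}
  land <- methods::new("LandscapeRaster",
                       broadleaf = matrix(0, 2, 2),
                       conifer = matrix(0, 2, 2), fineRes = 25,
                       origin = c(0, 0), period = "P1")
  cur <- matrix(c(0, 0, 1, 3), 2, 2)
  g <- aggregateCovariates(mkCurrent(cur), land, mkClimateConst(1, 1),
                           coarseRes = 50)
  expect_equal(covariates(g)$conn, 0.5)
})

test_that("cell ids follow the row-major 0-based convention", {
  land <- genLandscape(4, 6, 0.2, 0, seed = 3)
  g <- aggregateCovariates(mkCurrent(matrix(0, 4, 6)), land,
                           mkClimateConst(2, 3), coarseRes = 50)
  dat <- covariates(g)
  expect_equal(dat$cell, 0:5)
  expect_equal(dat$cell, dat$row * 3 + dat$col)
})

test_that("non-divisible resolutions are rejected", {
  land <- genLandscape(5, 5, 0.2, 0, seed = 1)
  expect_error(aggregateCovariates(mkCurrent(matrix(0, 5, 5)), land,
                                   mkClimateConst(2, 2), 60), "multiple")
  expect_error(aggregateCovariates(mkCurrent(matrix(0, 5, 5)), land,
                                   mkClimateConst(2, 2), 50),
               "divisible")
})

test_that("standardisation centres and scales with the population SD", {
  ## variable with values {0, 2}: population sd 1, so {-1, +1}
  gr <- mkRawGrid(4, 4, seed = 9)
  gr@data$conn <- rep(c(0, 2), length.out = nrow(gr@data))
  gs <- standardiseGrid(gr)
  expect_equal(sort(unique(covariates(gs)$conn)), c(-1, 1))
  p <- standardisation(gs)$conn
  expect_equal(p$mean, 1)
  expect_equal(p$sd, 1)
})

test_that("standardising twice is idempotent and composes parameters", {
  g1 <- mkStdGrid(6, 6, seed = 12)
  g2 <- standardiseGrid(g1)
  expect_equal(covariates(g2)$bl_cover, covariates(g1)$bl_cover,
               tolerance = 1e-10)
  expect_equal(standardisation(g2)$bl_cover$mean,
               standardisation(g1)$bl_cover$mean, tolerance = 1e-10)
})

test_that("a constant variable raises an explicit error", {
  gr <- mkRawGrid(4, 4, seed = 1)
  gr@data$soilm <- 5
  expect_error(standardiseGrid(gr), "constant")
})

test_that("unit conversion round-trips through the stored parameters", {
  g <- mkStdGrid(5, 5, seed = 30)
  std <- standardisation(g)
  x <- c(0.05, 0.10, 0.30)
  expect_equal(toNatural(std, "bl_cover",
                         toStandard(std, "bl_cover", x)), x)
})
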