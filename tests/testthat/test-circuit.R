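## Helpers building tiny deterministic landscapes.
onePixelLandscape <- function(nr, nc, bl = NULL, con = NULL) {
  b <- matrix(0, nr, nc); k <- matrix(0, nr, nc)
  if (!is.null(bl)) b[bl[1], bl[2]] <- 1
  if (!is.null(con)) k[con[1], con[2]] <- 1
  methods::new("LandscapeRaster", broadleaf = b, conifer = k,
               fineRes = 25, origin = c(0, 0), period = "P1")
}

test_that("resistance surface applies the matrix value and the union rule", {
  empty <- onePixelLandscape(5, 5)
  s <- buildResistance(empty)
  expect_true(all(s@resistance == 100))
  expect_equal(sum(s@sourceMask), 0)

  both <- onePixelLandscape(5, 5, bl = c(2, 2), con = c(4, 4))
  s2 <- buildResistance(both)
  expect_equal(sum(s2@sourceMask), 2)
  expect_true(s2@sourceMask[2, 2] && s2@sourceMask[4, 4])
  expect_equal(s2@resistance[2, 2], 1)
  expect_equal(s2@resistance[1, 1], 100)

  full <- genLandscape(4, 4, 1, 0, seed = 1)
  s3 <- buildResistance(full, rWood = 2)
  expect_true(all(s3@resistance == 2))
  expect_true(all(s3@sourceMask))
  expect_error(buildResistance(empty, rMatrix = 0), "positive")
})

test_that("empty source mask yields an all-zero current map", {
  s <- buildResistance(onePixelLandscape(6, 6))
  cm <- cumulativeCurrent(s, radiusM = 100)
  expect_true(all(currentMatrix(cm) == 0))
})

test_that("a two-pixel chain matches the series-resistor solution", {
  ## two woodland pixels at the ends of a 1 x 6 strip: a pure series
  ## circuit whose every edge carries the full unit current
  b <- matrix(0, 1, 6); b[1, 1] <- 1; b[1, 6] <- 1
  land <- methods::new("LandscapeRaster", broadleaf = b,
                       conifer = matrix(0, 1, 6), fineRes = 25,
                       origin = c(0, 0), period = "P1")
  s <- buildResistance(land)
  w <- circuitWindow(s, c(1, 6), radiusPx = 10)
  ## series resistance: edges (1,100)/2, 100, 100, 100, (100,1)/2
  expect_equal(w$v[1], 50.5 + 300 + 50.5, tolerance = 1e-10)
  expect_true(all(abs(w$nodeCurrent - 1) < 1e-10))
  oracle <- denseWindowOracle(w)
  expect_lt(max(abs(w$v - oracle$v)), 1e-8)
})

test_that("window solutions match the dense pseudo-inverse oracle", {
  set.seed(21)
  for (rep in 1:5) {
    land <- genLandscape(9, 9, stats::runif(1, 0.1, 0.4),
                         stats::runif(1, 0, 0.2),
                         clustering = stats::runif(1, 0.5, 2),
                         seed = 100 + rep)
    s <- buildResistance(land)
    wood <- which(s@sourceMask, arr.ind = TRUE)
    if (nrow(wood) < 2) next
    tgt <- wood[sample(nrow(wood), 1), ]
    w <- circuitWindow(s, tgt, radiusPx = 12)
    oracle <- denseWindowOracle(w)
    scale <- max(abs(oracle$nodeCurrent))
    expect_lt(max(abs(w$nodeCurrent - oracle$nodeCurrent)) / scale,
              1e-8)
  }
})

test_that("Kirchhoff balance holds at every node of a window solve", {
  land <- genLandscape(10, 10, 0.25, 0.1, clustering = 1.5, seed = 31)
  s <- buildResistance(land)
  wood <- which(s@sourceMask, arr.ind = TRUE)
  w <- circuitWindow(s, wood[1, ], radiusPx = 8)
  net <- nodeNetCurrent(w)
  interior <- setdiff(seq_along(w$cells),
                      c(which(w$inj > 0), w$targetLocal))
  expect_lt(max(abs(net[interior])), 1e-9)
  ## injected current equals current absorbed at the target
  expect_equal(net[w$targetLocal], -sum(w$inj), tolerance = 1e-9)
})

test_that("scaling all resistances leaves currents unchanged, scales voltages", {
  land <- genLandscape(8, 8, 0.3, 0, clustering = 1, seed = 41)
  s1 <- buildResistance(land, rMatrix = 100, rWood = 1)
  s2 <- buildResistance(land, rMatrix = 300, rWood = 3)
  wood <- which(s1@sourceMask, arr.ind = TRUE)
  w1 <- circuitWindow(s1, wood[2, ], radiusPx = 10)
  w2 <- circuitWindow(s2, wood[2, ], radiusPx = 10)
  expect_equal(w1$nodeCurrent, w2$nodeCurrent, tolerance = 1e-10)
  expect_equal(3 * w1$v, w2$v, tolerance = 1e-8)
})

test_that("a mirror-symmetric landscape yields a mirror-symmetric current map", {
  b <- matrix(0, 7, 8)
  b[3:5, 2:3] <- 1; b[3:5, 6:7] <- 1  # symmetric under column flip
  land <- methods::new("LandscapeRaster", broadleaf = b,
                       conifer = matrix(0, 7, 8), fineRes = 25,
                       origin = c(0, 0), period = "P1")
  cm <- currentMatrix(cumulativeCurrent(buildResistance(land), 150))
  expect_equal(cm, cm[, ncol(cm):1], tolerance = 1e-8)
})

test_that("total-injection normalisation rescales each window to unit input", {
  land <- genLandscape(8, 8, 0.3, 0, clustering = 1, seed = 51)
  s <- buildResistance(land)
  wood <- which(s@sourceMask, arr.ind = TRUE)
  wU <- circuitWindow(s, wood[1, ], 10, injection = "unit")
  wT <- circuitWindow(s, wood[1, ], 10, injection = "total")
  nSrc <- sum(wU$inj)
  expect_equal(wT$nodeCurrent * nSrc, wU$nodeCurrent, tolerance = 1e-10)
})

test_that("block subsampling approximates the full target set", {
  land <- genLandscape(20, 20, 0.2, 0, clustering = 2, seed = 61)
  s <- buildResistance(land)
  full <- currentMatrix(cumulativeCurrent(s, 150, blockSize = 1))
  blocked <- currentMatrix(cumulativeCurrent(s, 150, blockSize = 2))
  expect_equal(sum(blocked > 0) > 0, TRUE)
  ## same order of magnitude of total current (contributions rescaled)
  expect_lt(abs(log(sum(blocked) / sum(full))), log(2))
})

test_that("radius below the pixel size is rejected", {
  s <- buildResistance(genLandscape(5, 5, 0.2, 0, seed = 1))
  expect_error(cumulativeCurrent(s, radiusM = 10), "exceed")
})
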