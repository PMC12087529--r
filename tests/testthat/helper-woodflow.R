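## Shared fixtures and independent oracles, all built in code.

## Natural-unit covariate grid with random covariates.
mkRawGrid <- function(nr = 20, nc = 20, seed = 1) {
  set.seed(seed)
  mk <- function(per) {
    n <- nr * nc
    data.frame(cell = 0:(n - 1), row = rep(0:(nr - 1), each = nc),
               col = rep(0:(nc - 1), nr), period = per,
               bl_cover = stats::runif(n, 0, 0.4),
               con_cover = stats::runif(n, 0, 0.2),
               conn = stats::rexp(n),
               gdd5 = stats::rnorm(n), tcold = stats::rnorm(n),
               tseas = stats::rnorm(n), precip = stats::rnorm(n),
               soilm = stats::rnorm(n))
  }
  methods::new("CovariateGrid", data = rbind(mk("P1"), mk("P2")),
               coarseRes = 1000, dims = c(as.integer(nr),
                                          as.integer(nc)),
               standardisation = list())
}

## The same grid, standardised.
mkStdGrid <- function(nr = 20, nc = 20, seed = 1)
  standardiseGrid(mkRawGrid(nr, nc, seed))

## Direct simulation of a detection table for one species: visits get
## random cells, weeks and effort classes; response is Bernoulli with
## the closed-form probability. Returns the table and the grid.
simDetections <- function(n, truth, nr = 40, nc = 40, seed = 1) {
  grid <- mkStdGrid(nr, nc, seed)
  cov <- covariates(grid)
  idx <- sample(nrow(cov), n, replace = TRUE)
  vv <- cov[idx, ]
  vv$week <- sample(1:52, n, replace = TRUE)
  vv$list_length_class <- factor(
    sample(c("single", "short", "long"), n, TRUE),
    levels = c("single", "short", "long"))
  p <- visitProbability(truth, vv)
  det <- data.frame(visit_id = as.character(seq_len(n)),
                    cell_id = vv$cell, period = vv$period,
                    week = vv$week,
                    list_length_class = vv$list_length_class,
                    response = as.integer(stats::runif(n) < p),
                    stringsAsFactors = FALSE)
  list(det = det, grid = grid, p = p)
}

## Truth with every non-linear/latent component switched off.
flatTruth <- function(...) {
  truthParams(...,
              climateFuns = list(),
              phenologyFun = function(w) rep(0, length(w)),
              spatialSd = 0)
}

## Fixed-effects-only flat-prior model spec (logistic-regression limit).
flatSpec <- function(variant = "main")
  modelSpec(variant = variant, useClimate = FALSE, usePhenology = FALSE,
            useSpatial = FALSE, priorSdFixed = Inf)

## Dense pseudo-inverse oracle for one circuit window: voltages and
## node current magnitudes from the full (ungrounded) Laplacian
## pseudo-inverse, independent of the package's grounded sparse solve.
denseWindowOracle <- function(w) {
  m <- length(w$cells)
  L <- matrix(0, m, m)
  for (k in seq_along(w$edges$i)) {
    i <- w$edges$i[k]; j <- w$edges$j[k]; g <- w$edges$g[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  inj <- w$inj
  inj[w$targetLocal] <- inj[w$targetLocal] - sum(w$inj)
  v <- MASS::ginv(L) %*% inj
  v <- as.numeric(v - v[w$targetLocal])
  iEdge <- abs((v[w$edges$i] - v[w$edges$j]) * w$edges$g)
  cur <- numeric(m)
  for (k in seq_along(w$edges$i)) {
    cur[w$edges$i[k]] <- cur[w$edges$i[k]] + iEdge[k]
    cur[w$edges$j[k]] <- cur[w$edges$j[k]] + iEdge[k]
  }
  cur <- 0.5 * cur
  src <- which(w$inj > 0)
  cur[src] <- cur[src] + 0.5 * w$inj[src]
  cur[w$targetLocal] <- cur[w$targetLocal] + 0.5 * sum(w$inj)
  list(v = v, nodeCurrent = cur)
}

## Net signed current at every node of a solved window (Kirchhoff).
nodeNetCurrent <- function(w) {
  m <- length(w$cells)
  net <- numeric(m)
  iEdge <- (w$v[w$edges$i] - w$v[w$edges$j]) * w$edges$g
  for (k in seq_along(w$edges$i)) {
    net[w$edges$i[k]] <- net[w$edges$i[k]] + iEdge[k]
    net[w$edges$j[k]] <- net[w$edges$j[k]] - iEdge[k]
  }
  net
}

## Lag-1 spatial autocorrelation of a matrix (Moran-style statistic).
lag1Cor <- function(m) {
  stats::cor(c(as.vector(m[-1, ]), as.vector(m[, -1])),
             c(as.vector(m[-nrow(m), ]), as.vector(m[, -ncol(m)])))
}
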