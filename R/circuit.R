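## Omnidirectional moving-window circuit model.
##
## The landscape is a resistor lattice: every pixel is a node, joined
## to its 8 (optionally 4) neighbours by resistors whose value is the
## mean of the endpoint pixel resistances, scaled by sqrt(2) on
## diagonals. For each target woodland pixel a window of all pixels
## within a radius is cut out, unit current is injected at every other
## woodland pixel in the window, the target is grounded, and the
## grounded graph Laplacian is solved. Per-pixel current magnitudes
## are accumulated over all target windows into the cumulative
## current-flow map.

#' Build a resistance surface from the two woodland layers
#'
#' Merges broadleaf and conifer presence into a single woodland mask;
#' woodland pixels get resistance \code{rWood}, everything else
#' \code{rMatrix}. Only the habitat:matrix resistance ratio matters for
#' current patterns, so woodland resistance defaults to the unit
#' normalisation and the matrix to 100 times that.
#'
#' @param landscape a \code{LandscapeRaster} carrying both class layers.
#' @param rMatrix resistance of non-woodland pixels (> 0), default 100.
#' @param rWood resistance of woodland pixels (> 0), default 1.
#' @return a \code{\link{ResistanceSurface-class}} object.
#' @export
buildResistance <- function(landscape, rMatrix = 100, rWood = 1) {
  stopifnot(is(landscape, "LandscapeRaster"))
  if (rMatrix <= 0 || rWood <= 0)
    stop("resistances must be strictly positive")
  wood <- (landscape@broadleaf + landscape@conifer) > 0
  res <- matrix(rMatrix, nrow(wood), ncol(wood))
  res[wood] <- rWood
  new("ResistanceSurface", resistance = res, sourceMask = wood,
      fineRes = landscape@fineRes)
}

## Edge list of the lattice restricted to `cells` (global linear
## indices, column-major). Returns local endpoint indices and edge
## conductances (mean endpoint resistance, sqrt(2) on diagonals).
latticeEdges <- function(resist, cells, neighbours = 8) {
  nr <- nrow(resist); nc <- ncol(resist)
  rw <- ((cells - 1L) %% nr) + 1L
  cl <- ((cells - 1L) %/% nr) + 1L
  loc <- integer(nr * nc)
  loc[cells] <- seq_along(cells)
  dirs <- list(c(1, 0, 1), c(0, 1, 1))
  if (neighbours == 8)
    dirs <- c(dirs, list(c(1, 1, sqrt(2)), c(-1, 1, sqrt(2))))
  ii <- jj <- integer(0); gg <- numeric(0)
  for (d in dirs) {
    ri <- rw + d[1]; ci <- cl + d[2]
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    nb <- (ci - 1L) * nr + ri
    ok[ok] <- loc[nb[ok]] > 0L
    if (!any(ok)) next
    a <- loc[cells[ok]]
    b <- loc[nb[ok]]
    g <- 1 / (0.5 * (resist[cells[ok]] + resist[nb[ok]]) * d[3])
    ii <- c(ii, a); jj <- c(jj, b); gg <- c(gg, g)
  }
  list(i = ii, j = jj, g = gg)
}

## Sparse graph Laplacian from an edge list over m nodes.
edgeLaplacian <- function(edges, m) {
  deg <- numeric(m)
  ds <- rowsum(c(edges$g, edges$g), c(edges$i, edges$j))
  deg[as.integer(rownames(ds))] <- ds[, 1]
  Matrix::sparseMatrix(i = c(edges$i, edges$j, seq_len(m)),
                       j = c(edges$j, edges$i, seq_len(m)),
                       x = c(-edges$g, -edges$g, deg), dims = c(m, m))
}

#' Solve one moving-window circuit
#'
#' Cuts the window of all pixels within \code{radiusPx} of the target,
#' injects current at every woodland pixel in the window (the target
#' excluded), grounds the target and solves the grounded Laplacian
#' system. Exposed mainly so that window solutions can be audited
#' against independent oracles (Kirchhoff balance, dense pseudo-inverse
#' solutions).
#'
#' @param surface a \code{ResistanceSurface}.
#' @param target integer c(row, col), 1-based, of the target pixel.
#' @param radiusPx window radius in pixels.
#' @param neighbours 8 (default) or 4 neighbour lattice.
#' @param injection \code{"unit"} (1 A per source) or \code{"total"}
#'   (1 A split equally over sources).
#' @return NULL when the window holds no source, otherwise a list with
#'   \code{cells} (global indices), \code{v} (node voltages, target 0),
#'   \code{nodeCurrent} (per-node current magnitude), \code{inj}
#'   (injection vector), \code{targetLocal} and \code{edges}.
#' @export
circuitWindow <- function(surface, target, radiusPx, neighbours = 8,
                          injection = c("unit", "total")) {
  injection <- match.arg(injection)
  resist <- surface@resistance
  nr <- nrow(resist); nc <- ncol(resist)
  ti <- target[1]; tj <- target[2]
  fr <- floor(radiusPx)
  ir <- max(1, ti - fr):min(nr, ti + fr)
  jr <- max(1, tj - fr):min(nc, tj + fr)
  gi <- rep(ir, times = length(jr))
  gj <- rep(jr, each = length(ir))
  keep <- (gi - ti)^2 + (gj - tj)^2 <= radiusPx^2
  cells <- sort((gj[keep] - 1L) * nr + gi[keep])
  m <- length(cells)
  tLoc <- match((tj - 1L) * nr + ti, cells)
  srcLoc <- setdiff(which(surface@sourceMask[cells]), tLoc)
  if (length(srcLoc) == 0) return(NULL)

  edges <- latticeEdges(resist, cells, neighbours)
  L <- edgeLaplacian(edges, m)
  freeIdx <- seq_len(m)[-tLoc]
  inj <- numeric(m)
  inj[srcLoc] <- if (injection == "unit") 1 else 1 / length(srcLoc)
  v <- numeric(m)
  v[freeIdx] <- as.numeric(Matrix::solve(L[freeIdx, freeIdx],
                                         inj[freeIdx]))

  iEdge <- abs((v[edges$i] - v[edges$j]) * edges$g)
  nodeCur <- numeric(m)
  for (side in list(edges$i, edges$j)) {
    s <- rowsum(iEdge, side)
    nodeCur[as.integer(rownames(s))] <-
      nodeCur[as.integer(rownames(s))] + s[, 1]
  }
  nodeCur <- 0.5 * nodeCur
  nodeCur[srcLoc] <- nodeCur[srcLoc] + 0.5 * inj[srcLoc]
  nodeCur[tLoc] <- nodeCur[tLoc] + 0.5 * sum(inj)

  list(cells = cells, v = v, nodeCurrent = nodeCur, inj = inj,
       targetLocal = tLoc, edges = edges)
}

#' Cumulative current flow over all target windows
#'
#' Runs the moving-window circuit solve with every woodland pixel as a
#' target (or a per-block representative when \code{blockSize} > 1,
#' with that window's contribution scaled by the number of woodland
#' pixels in the block) and sums per-pixel current magnitudes into the
#' cumulative current-flow map. Fully deterministic.
#'
#' @param surface a \code{ResistanceSurface}.
#' @param radiusM window radius in metres; must exceed the pixel size.
#' @param blockSize integer >= 1; target subsampling block edge, a
#'   performance knob that trades solve count for resolution.
#' @param neighbours 8 (default) or 4 neighbour lattice.
#' @param injection source-strength convention, see
#'   \code{\link{circuitWindow}}.
#' @return a \code{\link{CurrentMap-class}} object.
#' @export
cumulativeCurrent <- function(surface, radiusM, blockSize = 1,
                              neighbours = 8,
                              injection = c("unit", "total")) {
  stopifnot(is(surface, "ResistanceSurface"))
  injection <- match.arg(injection)
  if (radiusM <= surface@fineRes)
    stop("radiusM must exceed the pixel edge length")
  if (blockSize < 1 || blockSize != round(blockSize))
    stop("blockSize must be a positive integer")
  radiusPx <- radiusM / surface@fineRes
  nr <- nrow(surface@resistance); nc <- ncol(surface@resistance)
  cur <- matrix(0, nr, nc)

  woodIdx <- which(surface@sourceMask)
  if (length(woodIdx) == 0)
    return(new("CurrentMap", current = cur, radiusM = radiusM,
               blockSize = blockSize, fineRes = surface@fineRes))

  if (blockSize == 1) {
    targets <- cbind(((woodIdx - 1L) %% nr) + 1L,
                     ((woodIdx - 1L) %/% nr) + 1L)
    weights <- rep(1, nrow(targets))
  } else {
    rw <- ((woodIdx - 1L) %% nr) + 1L
    cl <- ((woodIdx - 1L) %/% nr) + 1L
    block <- paste((rw - 1L) %/% blockSize, (cl - 1L) %/% blockSize)
    pick <- vapply(split(seq_along(woodIdx), block), function(sel) {
      bi <- rw[sel]; bj <- cl[sel]
      ci <- mean(range(bi)); cj <- mean(range(bj))
      sel[which.min((bi - ci)^2 + (bj - cj)^2)]
    }, 0L)
    counts <- vapply(split(seq_along(woodIdx), block), length, 0L)
    targets <- cbind(rw[pick], cl[pick])
    weights <- as.numeric(counts)
  }

  for (k in seq_len(nrow(targets))) {
    w <- circuitWindow(surface, targets[k, ], radiusPx, neighbours,
                       injection)
    if (is.null(w)) next
    cur[w$cells] <- cur[w$cells] + weights[k] * w$nodeCurrent
  }
  new("CurrentMap", current = cur, radiusM = radiusM,
      blockSize = blockSize, fineRes = surface@fineRes)
}

#' Effective resistance between two pixels
#'
#' Solves the whole-grid resistor network with unit current injected at
#' \code{src} and \code{tgt} grounded; the source voltage is the
#' two-point effective resistance. Used for Rayleigh-monotonicity
#' checks (lowering any resistance can never decrease the effective
#' conductance).
#'
#' @param surface a \code{ResistanceSurface}.
#' @param src,tgt integer c(row, col) pixel coordinates, 1-based.
#' @param neighbours 8 or 4 neighbour lattice.
#' @return effective resistance (ohm-like units).
#' @export
effectiveResistance <- function(surface, src, tgt, neighbours = 8) {
  resist <- surface@resistance
  nr <- nrow(resist); nc <- ncol(resist)
  cells <- seq_len(nr * nc)
  edges <- latticeEdges(resist, cells, neighbours)
  L <- edgeLaplacian(edges, length(cells))
  sIdx <- (src[2] - 1L) * nr + src[1]
  tIdx <- (tgt[2] - 1L) * nr + tgt[1]
  if (sIdx == tIdx) stop("src and tgt must differ")
  freeIdx <- cells[-tIdx]
  b <- numeric(length(cells)); b[sIdx] <- 1
  v <- numeric(length(cells))
  v[freeIdx] <- as.numeric(Matrix::solve(L[freeIdx, freeIdx],
                                         b[freeIdx]))
  v[sIdx]
}
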