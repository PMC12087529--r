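## End-to-end pipeline: simulate landscapes and records, compute
## connectivity, build visits, fit per-species occurrence models,
## classify associations, pool effects by meta-analysis and produce
## the cover x connectivity prediction surface. Each stage derives its
## own seed from the master seed, writes its outputs under the run
## directory, and logs counts into a manifest; re-running an identical
## config reproduces identical tables.

#' Default pipeline configuration
#'
#' A nested list covering every stage parameter. The defaults describe
#' a desk-scale study: an 80 x 80 fine grid (25 m pixels, 2 km square),
#' 200 m coarse cells, 10-pixel circuit radius, two recording schemes
#' with three species each, and pooled generating effects matching the
#' package's recovery experiments. The config round-trips through YAML
#' losslessly.
#'
#' @param seed master seed; every stage seed derives from it.
#' @return config list (class \code{woodflowConfig}).
#' @export
defaultConfig <- function(seed = 1) {
  structure(list(
    seed = seed,
    landscape = list(nrow = 80L, ncol = 80L, fineRes = 25,
                     coverBroadleaf = 0.10, coverConifer = 0.05,
                     clustering = 3, gainFrac = 0.08, lossFrac = 0.03),
    climate = list(smoothness = 6, interCor = 0.3, perturbSd = 0.3),
    circuit = list(radiusM = 250, rMatrix = 100, rWood = 1,
                   blockSize = 1L, neighbours = 8L,
                   injection = "unit", coarseRes = 200),
    species = list(nSchemes = 2L, perScheme = 3L, beta0 = -1,
                   beta0Sd = 0.5, muBlCover = 0.246, sdBlCover = 0.2,
                   muConn = 0.148, sdConn = 0.33, tauScheme = 0.03,
                   muInteraction = -0.050, sdInteraction = 0.1,
                   spatialSd = 0, rhoT = 0.8),
    visits = list(nVisits = 600L,
                  p1Window = c("1990-01-01", "1999-12-31"),
                  p2Window = c("2015-01-01", "2021-12-31"),
                  maxPrecision = 1000,
                  effortProbs = c(single = 0.4, short = 0.35,
                                  long = 0.25)),
    model = list(variant = "main", backend = "laplace",
                 useClimate = TRUE, usePhenology = TRUE,
                 useSpatial = TRUE, priorSdFixed = 1),
    meta = list(nIter = 1500L, nChains = 4L, warmup = 300L,
                associationFilter = "none"),
    surface = list(nGrid = 31L, baselineLogit = 0)
  ), class = "woodflowConfig")
}

#' Validate a pipeline configuration without executing it
#'
#' @param config a config list as from \code{\link{defaultConfig}}.
#' @return data.frame of violations (zero rows when valid).
#' @export
validateConfig <- function(config) {
  v <- list()
  flag <- function(stage, message)
    v[[length(v) + 1]] <<- data.frame(stage = stage, message = message,
                                      stringsAsFactors = FALSE)
  if (is.null(config$seed) || !is.finite(config$seed))
    flag("seed", "master seed missing or non-finite")
  ls <- config$landscape
  if (ls$nrow <= 0 || ls$ncol <= 0)
    flag("landscape", "shape must be positive")
  if (ls$coverBroadleaf + ls$coverConifer > 1)
    flag("landscape", "cover targets sum above 1")
  if (ls$clustering <= 0) flag("landscape", "clustering must be > 0")
  ci <- config$circuit
  if (ci$rMatrix <= 0 || ci$rWood <= 0)
    flag("circuit", "resistances must be strictly positive")
  if (ci$radiusM <= ls$fineRes)
    flag("circuit", "radiusM must exceed the pixel edge length")
  k <- ci$coarseRes / ls$fineRes
  if (abs(k - round(k)) > 1e-9)
    flag("circuit", "coarseRes must be a multiple of fineRes")
  else if (ls$nrow %% round(k) != 0 || ls$ncol %% round(k) != 0)
    flag("circuit", "fine grid not divisible into coarse cells")
  vs <- config$visits
  w1 <- as.Date(vs$p1Window); w2 <- as.Date(vs$p2Window)
  if (max(w1[1], w2[1]) <= min(w1[2], w2[2]))
    flag("visits", "period windows overlap")
  if (vs$nVisits <= 0) flag("visits", "nVisits must be positive")
  if (abs(sum(vs$effortProbs) - 1) > 1e-9)
    flag("visits", "effortProbs must sum to 1")
  sp <- config$species
  if (sp$nSchemes < 1 || sp$perScheme < 1)
    flag("species", "need at least one scheme and one species")
  if (!is.null(v) && length(v)) do.call(rbind, v)
  else data.frame(stage = character(), message = character())
}

#' Run the full pipeline
#'
#' Executes all stages in order, writing each stage's outputs and a
#' manifest (config, stage seeds, row counts, wall times) under
#' \code{outDir}. A failure in any stage aborts with the stage name;
#' outputs of completed stages remain on disk.
#'
#' @param config config list, see \code{\link{defaultConfig}}.
#' @param outDir run directory (created if needed).
#' @return invisibly, a list with the main in-memory results
#'   (covariate grid, species results, classifications, meta fits,
#'   prediction surface, manifest).
#' @export
runPipeline <- function(config = defaultConfig(), outDir) {
  viol <- validateConfig(config)
  if (nrow(viol) > 0)
    stop("invalid config: ",
         paste(viol$stage, viol$message, collapse = "; "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(outDir, "config.yaml"))
  manifest <- list(config_md5 =
    unname(tools::md5sum(file.path(outDir, "config.yaml"))))
  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  ms <- config$seed

  ## 1. landscapes
  ls <- config$landscape
  land1 <- tick("landscape_p1", genLandscape(
    ls$nrow, ls$ncol, ls$coverBroadleaf, ls$coverConifer,
    ls$clustering, fineRes = ls$fineRes, period = "P1",
    seed = deriveSeed(ms, 1)))
  land2 <- tick("landscape_p2", evolveLandscape(
    land1, ls$gainFrac, ls$lossFrac, seed = deriveSeed(ms, 2)))
  writeLandscape(land1, file.path(outDir, "landscape_P1"))
  writeLandscape(land2, file.path(outDir, "landscape_P2"))

  ## 2. climate
  k <- as.integer(round(config$circuit$coarseRes / ls$fineRes))
  nrC <- ls$nrow %/% k; ncC <- ls$ncol %/% k
  clim1 <- tick("climate_p1", genClimate(
    nrC, ncC, config$climate$smoothness, config$climate$interCor,
    period = "P1", seed = deriveSeed(ms, 3)))
  clim2 <- tick("climate_p2", perturbClimate(
    clim1, config$climate$perturbSd, config$climate$smoothness,
    period = "P2", seed = deriveSeed(ms, 4)))

  ## 3. connectivity + covariates
  ci <- config$circuit
  grids <- list()
  for (per in c("P1", "P2")) {
    land <- if (per == "P1") land1 else land2
    clim <- if (per == "P1") clim1 else clim2
    surf <- buildResistance(land, ci$rMatrix, ci$rWood)
    cur <- tick(paste0("current_", per), cumulativeCurrent(
      surf, ci$radiusM, ci$blockSize, ci$neighbours, ci$injection))
    writeCurrentMap(cur, file.path(outDir,
                                   paste0("current_", per, ".tsv")))
    grids[[per]] <- aggregateCovariates(cur, land, clim, ci$coarseRes)
  }
  covGrid <- tick("standardise", standardiseGrid(
    combineCovariateGrids(grids$P1, grids$P2)))
  writeCovariateGrid(covGrid, file.path(outDir, "covariates.csv"))

  ## 4. species truths + records
  sp <- config$species
  set.seed(deriveSeed(ms, 5))
  schemes <- data.frame(
    species_id = sprintf("sp%02d", seq_len(sp$nSchemes * sp$perScheme)),
    scheme_id = rep(sprintf("scheme%02d", seq_len(sp$nSchemes)),
                    each = sp$perScheme),
    stringsAsFactors = FALSE)
  schemeEff <- stats::rnorm(sp$nSchemes, 0, sp$tauScheme)
  truths <- list()
  for (i in seq_len(nrow(schemes))) {
    sIdx <- match(schemes$scheme_id[i],
                  sprintf("scheme%02d", seq_len(sp$nSchemes)))
    truths[[schemes$species_id[i]]] <- truthParams(
      beta0 = stats::rnorm(1, sp$beta0, sp$beta0Sd),
      betaBlCover = stats::rnorm(1, sp$muBlCover, sp$sdBlCover),
      betaConn = stats::rnorm(1, sp$muConn + schemeEff[sIdx],
                              sp$sdConn),
      betaBlConn = stats::rnorm(1, sp$muInteraction,
                                sp$sdInteraction),
      spatialSd = sp$spatialSd, rhoT = sp$rhoT)
  }
  vs <- config$visits
  gen <- tick("records", genRecords(
    truths, schemes, covGrid, vs$nVisits, vs$p1Window, vs$p2Window,
    effortProbs = vs$effortProbs, seed = deriveSeed(ms, 6)))
  writeRecords(gen$records, file.path(outDir, "records.csv"))
  manifest$n_records <- nrow(gen$records)

  ## 5. visits
  filt <- tick("filter", filterRecords(gen$records, vs$p1Window,
                                       vs$p2Window, vs$maxPrecision))
  visits <- tick("visits", buildVisits(filt))
  manifest$n_records_kept <- nrow(filt)
  manifest$n_visits <- nrow(visits)

  ## 6. per-species fits + classification
  md <- config$model
  spec <- modelSpec(variant = md$variant, useClimate = md$useClimate,
                    usePhenology = md$usePhenology,
                    useSpatial = md$useSpatial,
                    priorSdFixed = md$priorSdFixed)
  cfg <- inferenceConfig(backend = md$backend)
  results <- tick("fits", {
    out <- list()
    for (i in seq_len(nrow(schemes))) {
      spId <- schemes$species_id[i]; scId <- schemes$scheme_id[i]
      det <- tryCatch(detectionMatrix(visits, spId, scId),
                      error = function(e) NULL)
      out[[spId]] <- if (is.null(det))
        new("SpeciesModelResult", speciesId = spId, schemeId = scId,
            variant = md$variant, backend = md$backend,
            converged = FALSE, summary = data.frame(), nVisits = 0L)
      else fitSpeciesModel(det, covGrid, spec, cfg, speciesId = spId,
                           schemeId = scId, seed = deriveSeed(ms, 7))
    }
    out
  })
  utils::write.csv(resultsTable(results),
                   file.path(outDir, "species_effects.csv"),
                   row.names = FALSE)
  conv <- Filter(isConverged, results)
  manifest$n_species <- length(results)
  manifest$n_converged <- length(conv)
  assoc <- vapply(conv, classifyAssociation, "")
  utils::write.csv(data.frame(species_id = names(assoc),
                              association = unname(assoc)),
                   file.path(outDir, "associations.csv"),
                   row.names = FALSE)

  ## 7. meta-analysis per coefficient
  mt <- config$meta
  keep <- names(conv)
  if (mt$associationFilter != "none")
    keep <- names(assoc)[assoc %in%
                           c(mt$associationFilter, "both")]
  effFor <- function(effName) {
    rows <- lapply(conv[keep], function(r) {
      s <- r@summary; row <- s[s$effect == effName, ]
      if (nrow(row) == 0) return(NULL)
      data.frame(species_id = r@speciesId, scheme_id = r@schemeId,
                 estimate = row$mean, se = row$sd,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  metas <- tick("meta", {
    out <- list()
    for (eff in c("connectivity", "bl_cover",
                  "bl_cover:connectivity")) {
      e <- effFor(eff)
      if (is.null(e) || nrow(e) < 3)
        stop("too few converged species for meta-analysis of ", eff)
      out[[eff]] <- fitMeta(e, coefficient = eff, nIter = mt$nIter,
                            nChains = mt$nChains, warmup = mt$warmup,
                            seed = deriveSeed(ms, 8))
    }
    out
  })
  metaSumm <- do.call(rbind, lapply(names(metas), function(nm)
    cbind(coefficient = nm, effectSummary(metas[[nm]]))))
  utils::write.csv(metaSumm, file.path(outDir, "meta_summary.csv"),
                   row.names = FALSE)

  ## 8. prediction surface
  su <- config$surface
  surfPred <- tick("surface", predictSurface(
    metaDraws(metas[["bl_cover"]])$mu,
    metaDraws(metas[["connectivity"]])$mu,
    metaDraws(metas[["bl_cover:connectivity"]])$mu,
    covGrid = covGrid,
    coverValues = seq(min(covariates(covGrid)$bl_cover),
                      max(covariates(covGrid)$bl_cover),
                      length.out = su$nGrid),
    connValues = seq(min(covariates(covGrid)$conn),
                     max(covariates(covGrid)$conn),
                     length.out = su$nGrid),
    baselineLogit = su$baselineLogit))
  utils::write.csv(surfaceGrid(surfPred),
                   file.path(outDir, "surface.csv"), row.names = FALSE)

  manifest$stage_seconds <- stages
  manifest$r_version <- as.character(getRversion())
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  message("pipeline complete: ", manifest$n_visits, " visits, ",
          manifest$n_converged, "/", manifest$n_species,
          " species converged")
  invisible(list(covGrid = covGrid, results = results,
                 associations = assoc, metas = metas,
                 surface = surfPred, manifest = manifest))
}
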