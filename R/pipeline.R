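#' Pipeline configuration
#'
#' Fills defaults for the end-to-end synthetic study and validates that
#' every enabled stage has its parameters in range before anything runs.
#' The single `seed` drives every stage through stable per-stage derived
#' seeds.
#'
#' @param ... overrides of the defaults listed below.
#' @return validated config list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L, outDir = tempfile("urbanstress_run_"),
    stages = c("simulate", "sample", "compose", "score", "spatial",
               "map", "regress"),
    # simulate
    nSegments = 40L, extent = c(0, 0, 3000, 3000),
    archetypePatches = 12L,
    coefficients = defaultStressCoefficients(), intercept = 55,
    spatialRho = 0.7, noiseSd = 5,
    # sample
    interval = 50, headings = c(0, 90, 180, 270),
    districtPolygons = NULL,
    # score
    nRaters = 2L, raterNoiseSd = 3, nInit = 50L, errThresh = 10,
    streak = 6L, forestParams = list(nTrees = 100L, mtry = 6L),
    trainFrac = 0.667,
    # spatial
    threshold = "auto", metric = "manhattan", nPerm = 199L, alpha = 0.05,
    # map
    k = 6L, hexRadius = 150,
    # regress
    predictors = topElements(alias = FALSE))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  st <- cfg$stages
  if ("simulate" %in% st && cfg$nSegments < 1L)
    stop("config: nSegments must be >= 1")
  if ("sample" %in% st && cfg$interval <= 0)
    stop("config: interval must be positive")
  if ("score" %in% st && (cfg$nRaters < 1L || cfg$errThresh <= 0))
    stop("config: nRaters and errThresh must be positive")
  if ("spatial" %in% st && !identical(cfg$threshold, "auto") &&
      cfg$threshold <= 0)
    stop("config: threshold must be positive or 'auto'")
  if ("map" %in% st && (is.null(cfg$hexRadius) || cfg$hexRadius <= 0))
    stop("config: map stage requires a positive hexRadius")
  if ("regress" %in% st && length(cfg$predictors) < 1L)
    stop("config: regress stage needs predictors")
  invisible(cfg)
}

# Spatially coherent archetype assignment: seeded patch centers, nearest
# center wins, patches cycle through the archetype list. Gives the scene
# mix the block-by-block spatial structure of a real city district.
assignArchetypePatches <- function(points, archetypes, nPatches, seed) {
  xy <- coordsOf(points)
  n <- nrow(xy)
  ctr <- withSeed(seed, xy[sample.int(n, min(nPatches, n)), , drop = FALSE])
  lab <- rep_len(names(archetypes), nrow(ctr))
  d <- outer(xy[, 1], ctr[, 1], "-")^2 + outer(xy[, 2], ctr[, 2], "-")^2
  lab[max.col(-d, ties.method = "first")]
}

#' Run the full synthetic stress-mapping pipeline
#'
#' Executes simulate, sample, compose, score, spatial, map, regress in
#' order (subject to the configured stage toggles), writing every artifact
#' (CSV/GeoJSON/JSON) under `cfg$outDir` plus a manifest with the package
#' version, per-stage seeds, row counts and file checksums. Identical
#' config and seed reproduce identical checksums.
#'
#' The synthetic study emulates the target analysis: scenes drawn from
#' archetype patches, a latent stress field linear in element coverages
#' with a SAR-autocorrelated residual, and simulated raters whose
#' subjective scores are noisy readings of that field, scored through the
#' adversarial random-forest loop.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a result bundle: list with the per-stage objects
#'   (`points`, `scenes`, `consensus`, `moran`, `lisa`, `levels`, `hex`,
#'   `regression`, ...) and `manifest`.
#' @export
runPipeline <- function(cfg = pipelineConfig()) {
  validatePipelineConfig(cfg)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stages
  res <- list()
  counts <- list()
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(f) file.path(cfg$outDir, f)

  if ("simulate" %in% st) runStage("simulate", {
    res$network <- generateRoadNetwork(cfg$nSegments, cfg$extent,
                                        stageSeed(cfg$seed, "network"))
    writeNetworkGeoJSON(res$network, out("network.geojson"))
    counts$segments <- length(res$network@segments)
  })
  if ("sample" %in% st) runStage("sample", {
    pts <- pointsAlongNetwork(res$network, cfg$interval)
    if (!is.null(cfg$districtPolygons)) {
      pts <- assignDistricts(pts, cfg$districtPolygons)
      writeDistrictsGeoJSON(cfg$districtPolygons, out("districts.geojson"))
    }
    res$points <- pts
    writePointsCSV(pts, out("points.csv"))
    reqs <- enumerateViewRequests(pts, cfg$headings)
    utils::write.csv(reqs, out("requests.csv"), row.names = FALSE)
    counts$points <- nrow(pts); counts$requests <- nrow(reqs)
  })
  if ("compose" %in% st) runStage("compose", {
    arks <- defaultArchetypes()
    assign <- assignArchetypePatches(res$points, arks,
                                     cfg$archetypePatches,
                                     stageSeed(cfg$seed, "patches"))
    res$scenes <- generateSceneCompositions(res$points, arks, assign,
                                             stageSeed(cfg$seed, "scenes"))
    writeCompositionsCSV(res$scenes, out("compositions.csv"))
    counts$scenes <- ncol(res$scenes)
  })
  if ("score" %in% st) runStage("score", {
    W0 <- buildWeights(res$points, threshold = "auto", metric = cfg$metric)
    latent <- generateLatentStress(res$scenes, W0,
                                   coefficients = cfg$coefficients,
                                   intercept = cfg$intercept,
                                   spatialRho = cfg$spatialRho,
                                   noiseSd = cfg$noiseSd,
                                   seed = stageSeed(cfg$seed, "latent"))
    res$latent <- latent
    sessions <- lapply(seq_len(cfg$nRaters), function(r) {
      rseed <- stageSeed(cfg$seed, paste0("rater", r))
      noisy <- makeFieldRater(latent, cfg$raterNoiseSd, rseed)
      runScoringSession(noisy, res$scenes, nInit = cfg$nInit,
                        errThresh = cfg$errThresh, streak = cfg$streak,
                        forestParams = cfg$forestParams, seed = rseed,
                        raterId = paste0("rater", r))
    })
    res$sessions <- sessions
    res$consensus <- consensusScores(sessions)
    scored <- res$scenes
    stressScores(scored) <- res$consensus
    res$scenes <- scored
    writeScoresCSV(res$consensus, out("consensus_scores.csv"),
                   ids = res$points$id)
    sessionLogJSON(sessions, out("sessions.jsonl"))
    res$holdout <- evaluateHoldout(stressFractions(res$scenes),
                                    res$consensus,
                                    trainFrac = cfg$trainFrac,
                                    forestParams = cfg$forestParams,
                                    seed = stageSeed(cfg$seed, "holdout"))
    counts$interventions <- sum(vapply(sessions, slot, integer(1),
                                        "interventions"))
  })
  if ("spatial" %in% st) runStage("spatial", {
    res$W <- buildWeights(res$points, threshold = cfg$threshold,
                           metric = cfg$metric)
    writeWeightsCSV(res$W, out("weights.csv"))
    res$moran <- globalMoransI(res$consensus, res$W)
    res$scatter <- moranScatter(res$consensus, res$W)
    res$nbHist <- neighborCountHistogram(res$W)
    res$lisa <- localMoransI(res$consensus, res$W, nPerm = cfg$nPerm,
                              alpha = cfg$alpha,
                              seed = stageSeed(cfg$seed, "lisa"))
    utils::write.csv(data.frame(point_id = res$points$id,
                                Ii = res$lisa$Ii,
                                quadrant = res$lisa$quadrant,
                                p = res$lisa$p),
                     out("lisa.csv"), row.names = FALSE)
    jsonlite::write_json(res$moran[c("I", "E_I", "VAR_I", "Z", "p", "n",
                                     "mode")],
                         out("moran.json"), auto_unbox = TRUE, digits = NA)
  })
  if ("map" %in% st) runStage("map", {
    res$breaks <- jenksBreaks(res$consensus, cfg$k)
    res$levels <- levelTable(res$consensus, res$breaks)
    utils::write.csv(res$levels, out("level_table.csv"), row.names = FALSE)
    res$hex <- hexBin(res$points, res$consensus, cfg$hexRadius)
    writeHexGeoJSON(res$hex, cfg$hexRadius, out("hex_cells.geojson"))
    tiers <- levelToTier(classifyScores(res$consensus, res$breaks))
    res$tiers <- tierProfiles(res$scenes, tiers)
    utils::write.csv(data.frame(tier = rownames(res$tiers$profiles),
                                res$tiers$profiles, check.names = FALSE),
                     out("tier_profiles.csv"), row.names = FALSE)
    if (any(res$points$district != "unassigned", na.rm = TRUE)) {
      res$districtMeans <- districtMeans(res$points, res$consensus)
      utils::write.csv(res$districtMeans$districts,
                       out("district_means.csv"), row.names = FALSE)
    }
  })
  if ("regress" %in% st) runStage("regress", {
    Xr <- stressFractions(res$scenes)[, elementAlias(cfg$predictors),
                                      drop = FALSE]
    colnames(Xr) <- cfg$predictors
    res$regression <- olsFit(Xr, res$consensus)
    utils::write.csv(res$regression$coefficients,
                     out("regression_coefficients.csv"), row.names = FALSE)
    jsonlite::write_json(res$regression[c("r_squared", "adj_r_squared",
                                          "durbin_watson", "n")],
                         out("regression_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- sort(list.files(cfg$outDir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(cfg$outDir, files))
  manifest <- list(
    package = "urbanstress",
    version = as.character(utils::packageVersion("urbanstress")),
    seed = cfg$seed,
    stageSeeds = setNames(lapply(c("network", "patches", "scenes",
                                   "latent", "lisa"),
                                 function(s) stageSeed(cfg$seed, s)),
                          c("network", "patches", "scenes", "latent",
                            "lisa")),
    stages = st, rowCounts = counts,
    checksums = setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' @rdname runPipeline
#' @param latent numeric latent stress field per image.
#' @param noiseSd subjective noise SD.
#' @param seed rater seed.
#' @return `makeFieldRater()`: a rater function for
#'   [runScoringSession()] whose subjective score is a clipped noisy
#'   reading of the latent field.
#' @export
makeFieldRater <- function(latent, noiseSd, seed) {
  prof <- raterProfile(setNames(rep(0, 19L), cityscapesClasses()),
                       intercept = 0, noiseSd = max(noiseSd, 1e-12),
                       seed = seed)
  function(i, comp, pred) {
    eps <- raterNoise(prof, 1L)
    pmin(pmax(latent[i] + eps, 0), 100)
  }
}

sessionLogJSON <- function(sessions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in sessions) {
    recs <- s@records
    for (k in seq_len(nrow(recs)))
      writeLines(jsonlite::toJSON(
        c(list(rater = s@raterId), as.list(recs[k, ])),
        auto_unbox = TRUE, digits = NA, na = "null"), con)
  }
}
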