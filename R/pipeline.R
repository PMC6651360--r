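#' Construct an experiment configuration
#'
#' Defaults give the desk-scale experiment: a 400 x 400 px scene (1 m
#' GSD) with 60 bands, target prevalence 5\%, an 8 m cover correlation
#' length, 110 target + 200 background reference polygons stratified
#' 30/30/50, 30 MNF components, a 100-tree Random Forest and a centred
#' 10 ha (316 m) square control area. \code{fullScaleConfig()} returns
#' the full-scale variant (430 bands, larger scene).
#'
#' @param rows,cols Scene size in pixels.
#' @param bands Number of spectral bands.
#' @param gsd Ground sample distance (m).
#' @param prevalence Fraction of pixels with cover >= 0.2.
#' @param correlationLengthM Cover-field correlation length (m).
#' @param noiseSd Additive sensor noise SD.
#' @param nBackgroundEndmembers Background endmembers in the library.
#' @param separability Target-background separability scale.
#' @param nTarget,nBackground Reference polygon counts.
#' @param strataCounts Target counts per stratum (20-40, 50-70, 80-100).
#' @param radius Polygon radius (m).
#' @param minSpacing Minimum polygon centre spacing (m).
#' @param mnfK MNF components kept.
#' @param rfTrees Random Forest trees.
#' @param controlSideM Side of the centred square control area (m).
#' @param librarySeed Seed of the spectral library. The library is a
#'   study condition -- the synthetic species and its background flora --
#'   so it stays fixed across replicate experiments rather than deriving
#'   from the master seed.
#' @param masterSeed Master seed; all remaining stage seeds derive from
#'   it.
#' @return An \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(rows = 400L, cols = 400L, bands = 60L,
                             gsd = 1, prevalence = 0.05,
                             correlationLengthM = 8, noiseSd = 0.03,
                             nBackgroundEndmembers = 5L, separability = 0.15,
                             nTarget = 110L, nBackground = 200L,
                             strataCounts = c(30L, 30L, 50L),
                             radius = 2, minSpacing = 10,
                             mnfK = 30L, rfTrees = 100L,
                             controlSideM = 316,
                             librarySeed = 1L,
                             masterSeed = 1L) {
  new("ExperimentConfig",
      rows = as.integer(rows), cols = as.integer(cols),
      bands = as.integer(bands), gsd = gsd,
      prevalence = prevalence, correlationLengthM = correlationLengthM,
      noiseSd = noiseSd,
      nBackgroundEndmembers = as.integer(nBackgroundEndmembers),
      separability = separability,
      nTarget = as.integer(nTarget), nBackground = as.integer(nBackground),
      strataCounts = as.integer(strataCounts),
      radius = radius, minSpacing = minSpacing,
      mnfK = as.integer(mnfK), rfTrees = as.integer(rfTrees),
      controlSideM = controlSideM,
      librarySeed = as.integer(librarySeed),
      masterSeed = as.integer(masterSeed))
}

#' @rdname experimentConfig
#' @param ... Overrides passed to \code{experimentConfig}.
#' @export
fullScaleConfig <- function(...) {
  experimentConfig(rows = 1000L, cols = 1000L, bands = 430L,
                   controlSideM = 316, ...)
}

configToList <- function(config) {
  sn <- slotNames("ExperimentConfig")
  stats::setNames(lapply(sn, function(s) slot(config, s)), sn)
}

#' Read / write an experiment configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{readExperimentConfig}: an
#'   \linkS4class{ExperimentConfig}; \code{writeExperimentConfig}:
#'   invisibly, \code{path}.
#' @export
readExperimentConfig <- function(path) {
  do.call(experimentConfig, yaml::read_yaml(path))
}

#' @rdname readExperimentConfig
#' @param config An \linkS4class{ExperimentConfig}.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(configToList(config), path)
  invisible(path)
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(configToList(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

reportRow <- function(r) {
  ca <- r@confusionAreas
  data.frame(
    scenario = r@scenario, kappa = r@kappa, f1 = r@f1,
    tp_20_40 = r@stratumTPPct[["20-40"]],
    tp_50_70 = r@stratumTPPct[["50-70"]],
    tp_80_100 = r@stratumTPPct[["80-100"]],
    background_fp_pct = r@backgroundFPPct,
    map_area_pct = r@mapAreaPct,
    control_species_m2 = ca@controlSpeciesArea,
    control_background_m2 = ca@controlBackgroundArea,
    tp_m2 = ca@tpArea, fp_m2 = ca@fpArea,
    tn_m2 = ca@tnArea, fn_m2 = ca@fnArea,
    tp_pct = ca@tpPct, fp_pct = ca@fpPct,
    tn_pct = ca@tnPct, fn_pct = ca@fnPct,
    stringsAsFactors = FALSE
  )
}

#' Tabulate evaluation reports
#'
#' One row per scenario with the accuracy measures, stratum TP
#' percentages and zonal confusion columns.
#'
#' @param reports List of \linkS4class{EvaluationReport} objects.
#' @return A data.frame.
#' @export
reportTable <- function(reports) {
  do.call(rbind, lapply(reports, reportRow))
}

#' Run the full three-stage sampling-design experiment
#'
#' Simulates the scene and spectral library, renders and smooths the
#' cube, applies the MNF transform, places and annotates the reference
#' polygons, then runs the nine classification runs: Stage 0 (random
#' 50/50 polygon split), Stage 1 (cover-range scenarios SC0-SC4 against
#' the fixed validation set), scenario selection, and Stage 2
#' (training-set sizes 20/30/40 for the winning scenario). All
#' randomness derives from the config's master seed. When \code{outDir}
#' is given, rasters (ENVI), polygon files (GeoJSON + CSV), report
#' tables (CSV) and a JSON manifest (config hash, seeds) are written.
#'
#' @param config An \linkS4class{ExperimentConfig}.
#' @param outDir Output directory, or NULL to skip file output.
#' @param verbose Print stage progress.
#' @return List with the scene, design, fixed validation, per-run
#'   reports, the Stage-1 selection, the Stage-2 selection, and the
#'   report table.
#' @export
runExperiment <- function(config, outDir = NULL, verbose = FALSE) {
  stopifnot(is(config, "ExperimentConfig"))
  say <- function(...) if (verbose) message(...)
  seeds <- deriveSeeds(config@masterSeed,
                       c("scene", "noise", "place", "stage0",
                         "validation"))

  say("simulating scene")
  wl <- defaultWavelengths(config@bands)
  lib <- makeSpectralLibrary(config@nBackgroundEndmembers,
                             config@librarySeed, wl, config@separability)
  scene <- simulateCoverField(config@rows, config@cols,
                              config@correlationLengthM, config@prevalence,
                              seeds[["scene"]], config@gsd,
                              config@nBackgroundEndmembers)
  scene <- withTruthPatches(scene)
  cube <- renderCube(scene, lib, config@noiseSd, seeds[["noise"]])

  say("smoothing + MNF")
  win <- min(13L, config@bands)
  if (win %% 2L == 0L) win <- win - 1L
  smoothed <- savitzkyGolaySmooth(cube, win)
  mnf <- mnfTransform(smoothed)
  feat <- selectComponents(mnf, config@mnfK)

  say("placing reference polygons")
  design <- placeReferencePolygons(scene, config@nTarget,
                                   config@strataCounts, config@nBackground,
                                   seeds[["place"]], config@radius,
                                   config@minSpacing)
  control <- controlAreaSquare(sceneDim(scene), config@controlSideM,
                               config@gsd)
  patches <- truthPatches(scene)
  specs <- enumerateExperiment(config)

  runOne <- function(spec, trainIds, valIds) {
    assertNoLeakage(c(trainIds$target, trainIds$background),
                    c(valIds$target, valIds$background))
    ds <- assemblePixelDataset(feat, design,
                               c(trainIds$target, trainIds$background))
    model <- trainRF(ds, seed = spec@seed, ntree = config@rfTrees)
    map <- predictMap(model, feat)
    list(map = map,
         report = evaluateScenario(spec@name, map, design, valIds,
                                   patches, control))
  }

  reports <- list()
  maps <- list()

  say("Stage 0")
  s0 <- splitStage0(design, seeds[["stage0"]])
  m <- polygonMeta(design)
  asSets <- function(ids) list(target = ids[m$klass[match(ids, m$id)] == "target"],
                               background = ids[m$klass[match(ids, m$id)] == "background"])
  spec0 <- specs[[1]]
  r0 <- runOne(spec0, asSets(s0$train), asSets(s0$validation))
  reports[[spec0@name]] <- r0$report
  maps[[spec0@name]] <- r0$map

  say("Stage 1")
  fixedVal <- buildFixedValidation(design, seeds[["validation"]])
  stage1Specs <- specs[2:6]
  for (spec in stage1Specs) {
    tr <- buildStage1Training(design, fixedVal, spec)
    res <- runOne(spec, tr, fixedVal)
    reports[[spec@name]] <- res$report
    maps[[spec@name]] <- res$map
  }
  stage1Sel <- selectBestScenario(reports[vapply(stage1Specs,
                                                 function(s) s@name,
                                                 character(1))])
  best <- stage1Sel$overall
  bestSpec <- stage1Specs[[match(best,
                                 vapply(stage1Specs, function(s) s@name,
                                        character(1)))]]

  say("Stage 2 (best: ", best, ")")
  stage2Specs <- enumerateExperiment(config, best)[7:9]
  for (spec in stage2Specs) {
    tr <- buildStage2Training(design, fixedVal, bestSpec, spec@nTargetTrain)
    if (setequal(tr$target, buildStage1Training(design, fixedVal,
                                                bestSpec)$target)) {
      # identical polygon set to the winning Stage-1 run: reuse it
      src <- reports[[best]]
      src@scenario <- spec@name
      reports[[spec@name]] <- src
      maps[[spec@name]] <- maps[[best]]
    } else {
      res <- runOne(spec, tr, fixedVal)
      reports[[spec@name]] <- res$report
      maps[[spec@name]] <- res$map
    }
  }
  stage2Sel <- selectBestScenario(reports[vapply(stage2Specs,
                                                 function(s) s@name,
                                                 character(1))])

  tab <- reportTable(reports)
  out <- list(scene = scene, library = lib, design = design,
              fixedValidation = fixedVal, control = control,
              reports = reports, maps = maps,
              stage1Selection = stage1Sel, stage2Selection = stage2Sel,
              table = tab, config = config, seeds = seeds)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outDir, "reports.csv"),
                     row.names = FALSE)
    winners <- data.frame(
      stage = c(1L, 2L),
      accuracy_winner = c(stage1Sel$winners[["a"]], stage2Sel$winners[["a"]]),
      pixels_winner = c(stage1Sel$winners[["b"]], stage2Sel$winners[["b"]]),
      field_winner = c(stage1Sel$winners[["c"]], stage2Sel$winners[["c"]]),
      chosen = c(stage1Sel$overall, stage2Sel$overall)
    )
    utils::write.csv(winners, file.path(outDir, "winners.csv"),
                     row.names = FALSE)
    writeSampleDesign(design,
                      file.path(outDir, "design.geojson"),
                      file.path(outDir, "design.csv"))
    writeTruthPatchesGeoJSON(patches,
                             defaultGeotransform(config@rows, config@gsd),
                             file.path(outDir, "truth_patches.geojson"))
    writeENVI(feat, file.path(outDir, "mnf_components.bsq"))
    utils::write.csv(
      data.frame(component = seq_along(eigenvalues(mnf)),
                 eigenvalue = eigenvalues(mnf)),
      file.path(outDir, "mnf_eigenvalues.csv"), row.names = FALSE)
    manifest <- list(
      package = "coverwise",
      version = as.character(utils::packageVersion("coverwise")),
      configHash = configHash(config),
      masterSeed = config@masterSeed,
      seeds = as.list(seeds),
      bestStage1 = best,
      bestStage2 = stage2Sel$overall
    )
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Seeded end-to-end property replicates
#'
#' Runs the full experiment for \code{replicates} master seeds derived
#' from \code{baseSeed} and records, per replicate, the three expected
#' sampling-design effects: (i) training restricted to low/mid cover
#' (SC0) yields a higher control-area FP percentage than training on
#' dense stands only (SC4); (ii) SC4-trained runs score their highest
#' stratum TP percentage in the 80-100\% stratum; (iii) the 20-polygon
#' Stage-2 run yields a lower control-area TP percentage than both the
#' 30- and 40-polygon runs.
#'
#' @param config An \linkS4class{ExperimentConfig} (its master seed is
#'   replaced per replicate).
#' @param baseSeed Base seed for deriving replicate seeds.
#' @param replicates Number of replicates (default 10).
#' @param verbose Print progress.
#' @return A data.frame with one row per replicate and logical columns
#'   \code{sc0FpExceedsSc4}, \code{sc4BestHighStratum},
#'   \code{n20Underestimates}.
#' @export
runPropertyReplicates <- function(config = experimentConfig(),
                                  baseSeed = 1L, replicates = 10L,
                                  verbose = FALSE) {
  seeds <- deriveSeeds(baseSeed, paste0("rep", seq_len(replicates)))
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    cfg <- config
    cfg@masterSeed <- seeds[[i]]
    res <- runExperiment(cfg, verbose = FALSE)
    tab <- res$table
    get <- function(sc, col) tab[tab$scenario == sc, col]
    sc4 <- tab[tab$scenario == "SC4", ]
    best <- res$stage1Selection$overall
    s2 <- tab[grepl("_", tab$scenario), ]
    n <- as.integer(sub(".*_", "", s2$scenario))
    rows[[i]] <- data.frame(
      seed = seeds[[i]],
      best = best,
      kappa0 = get("STAGE0", "kappa"),
      f10 = get("STAGE0", "f1"),
      sc0FpExceedsSc4 = get("SC0", "fp_m2") > get("SC4", "fp_m2"),
      sc4BestHighStratum =
        which.max(c(sc4$tp_20_40, sc4$tp_50_70, sc4$tp_80_100)) == 3L,
      n20Underestimates = s2$tp_m2[n == 20] < s2$tp_m2[n == 30] &&
        s2$tp_m2[n == 20] < s2$tp_m2[n == 40]
    )
    if (verbose) message("replicate ", i, "/", replicates, " done (best ",
                         best, ")")
  }
  do.call(rbind, rows)
}

#' Run the package's worked-example and property acceptance suite
#'
#' Recomputes the published zonal percentage columns from the published
#' areas under the field-mapping normalization convention, checks the
#' winner-selection (majority) logic against the published winner
#' patterns, verifies the design-count arithmetic on a freshly simulated
#' scene, and (optionally) runs the seeded end-to-end property
#' replicates. Failures are report rows, not errors.
#'
#' @param seed Seed for the simulated-design checks.
#' @param replicates End-to-end replicates (0 to skip the slow part).
#' @param config Config for the end-to-end replicates.
#' @param verbose Print progress.
#' @return A data.frame with columns check, value, expected, pass.
#' @export
runAcceptanceSuite <- function(seed = 1L, replicates = 0L,
                               config = experimentConfig(),
                               verbose = FALSE) {
  rows <- list()
  add <- function(check, value, expected, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, expected = expected, pass = pass,
      stringsAsFactors = FALSE)
  }

  # Worked examples: percentage columns recomputed from published areas.
  za <- publishedZonalAreas()
  for (i in seq_len(nrow(za))) {
    areas <- new("ConfusionAreas",
                 controlSpeciesArea = za$control_species_m2[i],
                 controlBackgroundArea = za$control_background_m2[i],
                 tpArea = za$tp_m2[i], fpArea = za$fp_m2[i],
                 tnArea = za$tn_m2[i], fnArea = za$fn_m2[i])
    got <- confusionPercentages(areas)
    lab <- paste0(za$species[i], "/", za$scenario[i])
    ok <- got@tpPct == za$tp_pct[i] && got@fpPct == za$fp_pct[i] &&
      got@tnPct == za$tn_pct[i] && got@fnPct == za$fn_pct[i]
    add(paste0("zonal_pct_", lab),
        paste(got@tpPct, got@fpPct, got@tnPct, got@fnPct),
        paste(za$tp_pct[i], za$fp_pct[i], za$tn_pct[i], za$fn_pct[i]), ok)
  }

  # Winner-majority logic against the published patterns.
  wp <- publishedWinnerPatterns()
  for (i in seq_len(nrow(wp))) {
    got <- majorityWinner(c(a = wp$accuracy_winner[i],
                            b = wp$pixels_winner[i],
                            c = wp$field_winner[i]))
    add(paste0("winner_", wp$species[i], "_stage", wp$stage[i]),
        got, wp$chosen[i], got == wp$chosen[i])
  }

  # Design-count arithmetic on a simulated scene.
  scene <- simulateCoverField(config@rows, config@cols,
                              config@correlationLengthM, config@prevalence,
                              seed, config@gsd,
                              config@nBackgroundEndmembers)
  design <- placeReferencePolygons(scene, seed = seed)
  m <- polygonMeta(design)
  add("n_target_polygons", sum(m$klass == "target"), 110,
      sum(m$klass == "target") == 110)
  add("n_background_polygons", sum(m$klass == "background"), 200,
      sum(m$klass == "background") == 200)
  strata <- table(factor(m$stratum[m$klass == "target"],
                         levels = strataLevels))
  add("strata_counts", paste(strata, collapse = "/"), "30/30/50",
      all(strata == c(30, 30, 50)))
  add("nominal_target_pixels", sum(m$klass == "target") * 15L, 1650,
      sum(m$klass == "target") * 15L == 1650)
  specs <- enumerateExperiment(config)
  add("n_experiment_runs", length(specs), 9, length(specs) == 9)
  px <- rasterizeCircle(c(10.5, 10.5), 2,
                        defaultGeotransform(21L, 1), c(21L, 21L))
  add("circle_pixels_r2m", nrow(px), 13, nrow(px) == 13)

  if (replicates > 0L) {
    rep <- runPropertyReplicates(config, baseSeed = seed,
                                 replicates = replicates,
                                 verbose = verbose)
    add("sc0_fp_exceeds_sc4", sum(rep$sc0FpExceedsSc4), ">=0.8 of reps",
        sum(rep$sc0FpExceedsSc4) >= ceiling(0.8 * replicates))
    add("sc4_best_high_stratum", sum(rep$sc4BestHighStratum),
        ">=0.8 of reps",
        sum(rep$sc4BestHighStratum) >= ceiling(0.8 * replicates))
    add("n20_underestimates", sum(rep$n20Underestimates), ">=0.8 of reps",
        sum(rep$n20Underestimates) >= ceiling(0.8 * replicates))
  }
  do.call(rbind, rows)
}
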