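## Pipeline orchestration: a flat YAML config drives the staged run
## simulate -> indices -> decompose -> fit -> evaluate -> map -> report.
## Each stage writes its outputs plus a provenance sidecar and is re-entrant
## (skipped when outputs are current, unless forced).

PIPELINE_STAGES <- c("simulate", "indices", "decompose", "fit", "evaluate",
                     "map", "report")

pipelineDefaults <- function() {
  list(
    out_dir = "phenocube_run",
    ## scene generation
    grid_rows = 64L, grid_cols = 64L,
    start_date = "2016-01-01", end_date = "2024-12-31",
    revisit_days = 5, dropout_prob = 0.68,
    cloud_beta_params = c(0.1, 20), gap_prob = 0.04,
    noise_sd = 0.02, noise_type = "additive",
    rain_rate_per_year = 4, rain_magnitude_mean = 1,
    n_fires = 2L, pixel_size = 10,
    n_waypoints = 400L, stratified_waypoints = TRUE,
    write_rasters = FALSE,
    ## quality thresholds
    cloud_max = 0.03, valid_min = 0.90,
    impute_policy = "linear",
    ## decomposition
    indices = c("NDVI", "EVI", "NDWI", "NBR"),
    retained_k = 6L, svd_method = "exact",
    ## modelling
    criterion = "BIC", n_boot = 10L, train_fraction = 2 / 3,
    fit_neural_net = TRUE,
    logit_sign = "standard", probability_threshold = 0.5,
    ## randomness
    seed = 42L)
}

#' Read and validate a pipeline configuration
#'
#' Loads a flat YAML document, fills unset keys with the package defaults
#' and rejects unknown keys. The returned list drives [runStage()] and is
#' echoed into every provenance sidecar.
#'
#' @param path YAML file path, or NULL for pure defaults
#' @param overrides named list applied after the file (e.g. from the
#'   command line)
#' @return validated configuration list
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- pipelineDefaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(c(user, overrides)), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- modifyList(cfg, user)
  cfg <- modifyList(cfg, overrides)
  stopifnot_scalar(cfg$cloud_max, "cloud_max", min = 0, max = 1)
  stopifnot_scalar(cfg$valid_min, "valid_min", min = 0, max = 1)
  stopifnot_scalar(cfg$probability_threshold, "probability_threshold",
                   min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  if (!all(toupper(cfg$indices) %in% INDEX_NAMES))
    stop("indices must be drawn from EVI, NBR, NDVI, NDWI", call. = FALSE)
  if (!(cfg$logit_sign %in% c("standard", "printed")))
    stop("logit_sign must be 'standard' or 'printed'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

sceneConfigFromPipeline <- function(cfg) {
  sceneConfig(gridRows = cfg$grid_rows, gridCols = cfg$grid_cols,
              startDate = cfg$start_date, endDate = cfg$end_date,
              revisitDays = cfg$revisit_days, dropoutProb = cfg$dropout_prob,
              cloudBetaParams = cfg$cloud_beta_params, gapProb = cfg$gap_prob,
              noiseSd = cfg$noise_sd, noiseType = cfg$noise_type,
              rainRatePerYear = cfg$rain_rate_per_year,
              rainMagnitudeMean = cfg$rain_magnitude_mean,
              nFires = cfg$n_fires, pixelSize = cfg$pixel_size,
              seed = cfg$seed)
}

stageDir <- function(cfg, stage) file.path(cfg$out_dir, stage)

stageOutputs <- function(cfg, stage) {
  d <- stageDir(cfg, stage)
  switch(stage,
    simulate = file.path(d, c("scene.rds", "waypoints.csv")),
    indices = file.path(d, "matrices.rds"),
    decompose = file.path(d, c("decompositions.rds", "singular_values.csv")),
    fit = file.path(d, c("model.json", "features.rds")),
    evaluate = file.path(d, "report.csv"),
    map = file.path(d, c("probability.tif", "occurrence.tif",
                         "strata_summary.csv", "strata_accuracy.csv")),
    report = file.path(d, "overview.json"))
}

requireUpstream <- function(cfg, stage, upstream) {
  missing <- !file.exists(stageOutputs(cfg, upstream))
  if (any(missing))
    stop(sprintf("stage '%s' needs outputs of stage '%s'; run that stage first",
                 stage, upstream), call. = FALSE)
}

writeProvenance <- function(cfg, stage, inputs = character(0)) {
  d <- stageDir(cfg, stage)
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  doc <- list(stage = stage, seed = cfg$seed,
              config = cfg,
              config_md5 = unname(tools::md5sum(tmp)),
              input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              package_version = as.character(utils::packageVersion("phenocube")))
  unlink(tmp)
  jsonlite::write_json(doc, file.path(d, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run one pipeline stage
#'
#' Stages: simulate (synthetic scene + waypoints), indices (quality filter +
#' spatiotemporal matrices), decompose (truncated SVD per index), fit
#' (stepwise logistic at the waypoints), evaluate (bootstrap report, logistic
#' and neural net), map (probability surface, occurrence map, stratum
#' tables), report (bundled overview). Each stage writes a provenance
#' sidecar (config echo + hash, input hashes, seed, package version) and is
#' skipped when its outputs already exist, unless `force = TRUE`.
#'
#' @param stage one of the stage names above
#' @param config list from [readPipelineConfig()]
#' @param force rerun even if outputs are current?
#' @return character vector of the stage's output paths, invisibly
#' @export
runStage <- function(stage, config, force = FALSE) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  cfg <- config
  outs <- stageOutputs(cfg, stage)
  if (!force && all(file.exists(outs))) {
    message(sprintf("stage '%s' is up to date; skipping (use force = TRUE to rerun)",
                    stage))
    return(invisible(outs))
  }
  d <- stageDir(cfg, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  if (stage == "simulate") {
    scene <- simulateScene(sceneConfigFromPipeline(cfg))
    saveRDS(scene, outs[1])
    wp <- sampleWaypoints(scene, cfg$n_waypoints,
                          stratified = cfg$stratified_waypoints,
                          seed = childSeed(cfg$seed, 11L))
    writeWaypointsCsv(wp, outs[2])
    if (isTRUE(cfg$write_rasters))
      writeSceneRasters(scene, file.path(d, "rasters"))
    writeProvenance(cfg, stage)
  } else if (stage == "indices") {
    requireUpstream(cfg, stage, "simulate")
    scene <- readRDS(stageOutputs(cfg, "simulate")[1])
    mats <- buildIndexMatrices(reflectanceCube(scene), cfg$indices,
                               cfg$cloud_max, cfg$valid_min, cfg$impute_policy)
    saveRDS(mats, outs[1])
    jsonlite::write_json(
      lapply(mats, function(m) list(index = indexName(m),
                                    dates = nrow(matrixValues(m)),
                                    pixels = ncol(matrixValues(m)),
                                    imputed = m@nImputed,
                                    cloud_max = cfg$cloud_max,
                                    valid_min = cfg$valid_min,
                                    impute_policy = cfg$impute_policy)),
      file.path(d, "matrices.json"), auto_unbox = TRUE, pretty = TRUE)
    writeProvenance(cfg, stage, stageOutputs(cfg, "simulate"))
  } else if (stage == "decompose") {
    requireUpstream(cfg, stage, "indices")
    mats <- readRDS(stageOutputs(cfg, "indices")[1])
    dec <- lapply(mats, decomposeMatrix, k = cfg$retained_k,
                  method = cfg$svd_method, seed = childSeed(cfg$seed, 21L))
    saveRDS(dec, outs[1])
    writeDecompositionSummaryCsv(dec, outs[2])
    writeProvenance(cfg, stage, stageOutputs(cfg, "indices"))
  } else if (stage == "fit") {
    requireUpstream(cfg, stage, "decompose")
    requireUpstream(cfg, stage, "simulate")
    dec <- readRDS(stageOutputs(cfg, "decompose")[1])
    wp <- readWaypointsCsv(stageOutputs(cfg, "simulate")[2])
    feats <- extractFeatures(dec, cfg$retained_k)
    labelled <- featuresAtWaypoints(feats, wp)
    saveRDS(list(table = feats, labelled = labelled), outs[2])
    model <- stepwiseLogistic(
      as.matrix(labelled[, colnames(featureMatrix(feats)), drop = FALSE]),
      labelled$label, criterion = cfg$criterion)
    writeLogisticModelJson(model, outs[1])
    writeProvenance(cfg, stage,
                    c(stageOutputs(cfg, "decompose"),
                      stageOutputs(cfg, "simulate")))
  } else if (stage == "evaluate") {
    requireUpstream(cfg, stage, "fit")
    fitArtifacts <- readRDS(stageOutputs(cfg, "fit")[2])
    labelled <- fitArtifacts$labelled
    X <- as.matrix(labelled[, colnames(featureMatrix(fitArtifacts$table)),
                            drop = FALSE])
    reports <- list(bootstrapEvaluate(
      function(x, y) stepwiseLogistic(x, y, criterion = cfg$criterion),
      X, labelled$label, nBoot = cfg$n_boot,
      trainFraction = cfg$train_fraction,
      seed = childSeed(cfg$seed, 31L), modelLabel = "LR"))
    if (isTRUE(cfg$fit_neural_net)) {
      nnSeed <- childSeed(cfg$seed, 32L)
      reports <- c(reports, list(bootstrapEvaluate(
        function(x, y) fitNeuralNet(x, y, seed = nnSeed),
        X, labelled$label, nBoot = cfg$n_boot,
        trainFraction = cfg$train_fraction,
        seed = childSeed(cfg$seed, 31L), modelLabel = "NN")))
    }
    writeEvaluationReport(reports, outs[1])
    saveRDS(reports, file.path(d, "reports.rds"))
    writeProvenance(cfg, stage, stageOutputs(cfg, "fit"))
  } else if (stage == "map") {
    requireUpstream(cfg, stage, "fit")
    requireUpstream(cfg, stage, "simulate")
    fitArtifacts <- readRDS(stageOutputs(cfg, "fit")[2])
    model <- readLogisticModelJson(stageOutputs(cfg, "fit")[1])
    scene <- readRDS(stageOutputs(cfg, "simulate")[1])
    wp <- readWaypointsCsv(stageOutputs(cfg, "simulate")[2])
    surface <- predictSurface(model, fitArtifacts$table,
                              logitSign = cfg$logit_sign)
    occ <- thresholdMap(surface, cfg$probability_threshold)
    writeSurfaceTiff(surface, outs[1])
    writeSurfaceTiff(occ, outs[2], geo = geoMeta(surface))
    write.csv(strataSummary(surface, strataMap(scene)), outs[3],
              row.names = FALSE)
    write.csv(strataAccuracy(surface, wp, cfg$probability_threshold),
              outs[4], row.names = FALSE)
    saveRDS(surface, file.path(d, "surface.rds"))
    writeProvenance(cfg, stage,
                    c(stageOutputs(cfg, "fit"), stageOutputs(cfg, "simulate")))
  } else if (stage == "report") {
    requireUpstream(cfg, stage, "evaluate")
    requireUpstream(cfg, stage, "map")
    for (f in c(stageOutputs(cfg, "evaluate"),
                stageOutputs(cfg, "map")[3:4]))
      file.copy(f, file.path(d, basename(f)), overwrite = TRUE)
    reports <- readRDS(file.path(stageDir(cfg, "evaluate"), "reports.rds"))
    lr <- reports[[1]]@metrics
    val <- lr[lr$role == "validation", ]
    overview <- list(
      validation_accuracy = val$mean[val$metric == "accuracy"],
      validation_auc = val$mean[val$metric == "auc"],
      n_boot = reports[[1]]@nBoot,
      threshold = cfg$probability_threshold)
    jsonlite::write_json(overview, outs[1], auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    writeProvenance(cfg, stage)
  }
  message(sprintf("stage '%s' finished in %.1f s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(outs)
}

#' Run the whole pipeline
#'
#' Executes every stage in order with shared config; see [runStage()].
#'
#' @param config list from [readPipelineConfig()]
#' @param force rerun stages whose outputs already exist?
#' @return named list of stage output paths, invisibly
#' @export
runPipeline <- function(config, force = FALSE) {
  out <- lapply(setNames(PIPELINE_STAGES, PIPELINE_STAGES),
                runStage, config = config, force = force)
  invisible(out)
}
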