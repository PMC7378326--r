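#' Pipeline run configuration
#'
#' Single configuration object driving the end-to-end analysis
#' (simulate -> crop/detect -> evaluate -> calibrate -> map). Stages read
#' their inputs from `out_dir`, so each stage is re-runnable from the files
#' the previous one persisted, and an identical (config, seed) reruns
#' byte-identically.
#'
#' @param out_dir output directory for all stage artifacts.
#' @param orchard an [orchard_config()] (used by the simulate stage).
#' @param detector a [detector_params()].
#' @param diameter_m circular tree-mask diameter in meters (default 1).
#' @param iou_min IoU criterion for matching detections to truth.
#' @param score_floor score threshold when counting detections.
#' @param bin_edges yield-map class bins (see [per_tree_layer()]).
#' @param raster_path,tree_layer_path,truth_path optional paths to existing
#'   inputs; defaults point at the simulate stage's outputs in `out_dir`.
#' @param seed integer seed for the whole run.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir,
                       orchard = orchard_config(),
                       detector = detector_params(),
                       diameter_m = 1,
                       iou_min = 0.5,
                       score_floor = 0.5,
                       bin_edges = c(0, 20, 30, 40, 60, 80, 120, Inf),
                       raster_path = file.path(out_dir, "scene.tif"),
                       tree_layer_path = file.path(out_dir, "trees.geojson"),
                       truth_path = file.path(out_dir, "tree_truth.csv"),
                       seed = orchard$seed) {
  structure(
    list(out_dir = out_dir, orchard = orchard, detector = detector,
         diameter_m = diameter_m, iou_min = iou_min, score_floor = score_floor,
         bin_edges = bin_edges, raster_path = raster_path,
         tree_layer_path = tree_layer_path, truth_path = truth_path,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Simulate stage: generate and persist a synthetic scene
#'
#' @param config a [run_config()].
#' @return the `scene_bundle`, invisibly; files under `config$out_dir`.
#' @export
run_simulate <- function(config) {
  oc <- config$orchard
  oc$seed <- config$seed
  bundle <- simulate_orchard(oc)
  paths <- write_scene(bundle, config$out_dir)
  log_stage("simulate", "%d trees, %d fruits (%d visible) -> %s",
            nrow(bundle$trees), nrow(bundle$fruits), sum(bundle$fruits$visible),
            config$out_dir)
  invisible(bundle)
}

read_tree_layer <- function(config) {
  if (!file.exists(config$tree_layer_path)) {
    stopf("tree layer not found: %s (run the simulate stage or point tree_layer_path at your file)",
          config$tree_layer_path)
  }
  layer <- read_vector(config$tree_layer_path)
  trees <- layer$attributes
  trees$x <- layer$geometry[, 1]
  trees$y <- layer$geometry[, 2]
  trees
}

#' Detect stage: per-tree counting over the raster
#'
#' @param config a [run_config()].
#' @return list as from [count_per_tree()], invisibly; writes
#'   `tree_counts.csv` and `detections.csv`.
#' @export
run_detect <- function(config) {
  if (!file.exists(config$raster_path)) stopf("raster not found: %s", config$raster_path)
  raster <- read_raster(config$raster_path)
  trees <- read_tree_layer(config)
  det <- function(tile) reference_blob_detect(tile, config$detector)
  res <- count_per_tree(raster, trees, det,
                        diameter_m = config$diameter_m,
                        score_floor = config$score_floor)
  utils::write.csv(res$counts, file.path(config$out_dir, "tree_counts.csv"), row.names = FALSE)
  write_detections_csv(res$detections, file.path(config$out_dir, "detections.csv"))
  log_stage("detect", "%d trees, %d detections counted",
            nrow(res$counts), sum(res$counts$count, na.rm = TRUE))
  invisible(res)
}

#' Evaluate stage: per-tree detection metrics against scene truth
#'
#' Each tree tile is one evaluation picture: its truth boxes are the scene
#' truth boxes whose centers fall inside the tree's circular mask, its
#' `Nfp` is the number of those boxes, and detections come from the detect
#' stage. Produces the per-picture metrics table with an Avg row.
#'
#' @param config a [run_config()].
#' @param detections optional result of [run_detect()] (re-run otherwise).
#' @return the metrics table, invisibly; writes `metrics.csv`.
#' @export
run_evaluate <- function(config, detections = NULL) {
  truth_xml <- file.path(config$out_dir, "scene_truth.xml")
  if (!file.exists(truth_xml)) stopf("scene truth not found: %s", truth_xml)
  truth <- read_voc(truth_xml)
  raster <- read_raster(config$raster_path)
  trees <- read_tree_layer(config)
  if (is.null(detections)) detections <- run_detect(config)
  cx <- (truth$boxes$xmin + truth$boxes$xmax) / 2
  cy <- (truth$boxes$ymin + truth$boxes$ymax) / 2
  centers <- pixel_to_world(raster$transform, cbind(cx, cy))
  rows <- lapply(seq_len(nrow(trees)), function(i) {
    r2 <- (config$diameter_m / 2)^2
    sel <- (centers[, 1] - trees$x[i])^2 + (centers[, 2] - trees$y[i])^2 <= r2
    tb <- truth$boxes[sel, , drop = FALSE]
    db <- detections$detections[[trees$tree_id[i]]]
    db <- if (is.null(db)) truth$boxes[0, ] else db$boxes
    m <- match_detections(db, tb, config$iou_min)
    detection_metrics(m, nfp = nrow(tb), picture_id = trees$tree_id[i])
  })
  tab <- metrics_table(do.call(rbind, rows))
  write_metrics_csv(tab, file.path(config$out_dir, "metrics.csv"))
  log_stage("evaluate", "%d pictures, Avg F1 = %.2f",
            nrow(tab) - 1L, tab$f1[nrow(tab)])
  invisible(tab)
}

#' Calibrate stage: visible-to-total regression from counts and truth
#'
#' @param config a [run_config()].
#' @return the `regression_fit`, invisibly; writes `calibration.json` and
#'   `calibration_pairs.csv`.
#' @export
run_calibrate <- function(config) {
  counts_csv <- file.path(config$out_dir, "tree_counts.csv")
  if (!file.exists(counts_csv)) stopf("tree counts not found: %s (run the detect stage first)", counts_csv)
  if (!file.exists(config$truth_path)) stopf("per-tree truth not found: %s", config$truth_path)
  counts <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  truth <- utils::read.csv(config$truth_path, stringsAsFactors = FALSE)
  pairs <- merge(
    data.frame(tree_id = counts$tree_id, detected = counts$count),
    data.frame(tree_id = truth$tree_id, reference = truth$total),
    by = "tree_id"
  )
  pairs <- pairs[!is.na(pairs$detected), , drop = FALSE]
  fit <- fit_calibration(pairs)
  utils::write.csv(pairs, file.path(config$out_dir, "calibration_pairs.csv"), row.names = FALSE)
  jsonlite::write_json(
    fit[c("slope", "intercept", "r_squared", "mae", "rmse", "n", "method")],
    file.path(config$out_dir, "calibration.json"),
    auto_unbox = TRUE, digits = NA
  )
  log_stage("calibrate", "slope = %.3f, R^2 = %.3f over %d trees", fit$slope, fit$r_squared, fit$n)
  invisible(fit)
}

#' Map stage: per-tree and per-row yield layers
#'
#' @param config a [run_config()].
#' @return list with the two [geo_features()] layers, invisibly; writes
#'   GeoJSON and Shapefile versions of both.
#' @export
run_map <- function(config) {
  counts_csv <- file.path(config$out_dir, "tree_counts.csv")
  if (!file.exists(counts_csv)) stopf("tree counts not found: %s (run the detect stage first)", counts_csv)
  counts <- utils::read.csv(counts_csv, stringsAsFactors = FALSE)
  trees <- read_tree_layer(config)
  tree_layer <- per_tree_layer(trees, counts, config$bin_edges)
  row_layer <- per_row_layer(tree_layer)
  for (fmt in c("geojson", "shp")) {
    write_vector(tree_layer, file.path(config$out_dir, paste0("yield_per_tree.", fmt)))
    write_vector(row_layer, file.path(config$out_dir, paste0("yield_per_row.", fmt)))
  }
  log_stage("map", "%d tree features, %d row features",
            n_features(tree_layer), n_features(row_layer))
  invisible(list(per_tree = tree_layer, per_row = row_layer))
}

#' Run the full pipeline
#'
#' simulate -> detect -> evaluate -> calibrate -> map, writing a run
#' manifest (config snapshot, package version, seed, per-stage record
#' counts and timings). Identical (config, seed) produce identical outputs
#' byte-for-byte, apart from the manifest's timings.
#'
#' @param config a [run_config()].
#' @return named list of stage results, invisibly; files under
#'   `config$out_dir` including `manifest.json`.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  timings <- list()
  records <- list()
  tick <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stopf("stage '%s' failed: %s", stage, conditionMessage(e))
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }
  stages$simulate <- tick("simulate", function() run_simulate(config))
  records$simulate <- nrow(stages$simulate$trees)
  stages$detect <- tick("detect", function() run_detect(config))
  records$detect <- nrow(stages$detect$counts)
  stages$evaluate <- tick("evaluate", function() run_evaluate(config, stages$detect))
  records$evaluate <- nrow(stages$evaluate) - 1L
  stages$calibrate <- tick("calibrate", function() run_calibrate(config))
  records$calibrate <- stages$calibrate$n
  stages$map <- tick("map", function() run_map(config))
  records$map <- n_features(stages$map$per_tree)
  manifest <- list(
    package_version = as.character(utils::packageVersion("orchardyield")),
    seed = config$seed,
    config = config[c("diameter_m", "iou_min", "score_floor", "bin_edges")],
    orchard = unclass(config$orchard),
    detector = unclass(config$detector),
    stage_records = records,
    stage_seconds = timings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stages)
}
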