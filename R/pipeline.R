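# Pipeline orchestration: synthesize -> extract features -> train RGB ->
# train fusion -> predict -> post-process -> evaluate, driven by a single
# YAML-able configuration with one global seed. Stage outputs are cached by
# checksums of their inputs and configuration, so re-running an unchanged
# stage is a no-op.

#' Pipeline configuration
#'
#' All module configurations plus paths and the global seed, as one nested
#' list. `scene`, `rgb`, `fusion` accept the argument lists of
#' [scene_config()], [rgb_train_config()], [fusion_config()]; unspecified
#' entries take those defaults, with every module seed derived from the
#' global seed.
#'
#' @param out_dir run directory for scenes, features, models and reports.
#' @param seed global seed; all stage seeds derive from it.
#' @param scene,rgb,fusion named lists of overrides for the module configs.
#' @param n_train_plots,n_test_plots scene sizes.
#' @param crown_split_fraction crown-level train fraction (0.75 mirrors a
#'   75/25 split; the RGB and fusion stages use their own 80/20 validation
#'   splits).
#' @param bad_band_windows list of inclusive nm intervals.
#' @param n_bins,max_height pseudo-waveform binning.
#' @param lower_percentile,upper_percentile height anomaly filter bounds.
#' @param threshold,other_mass open-set post-processing parameters.
#' @param hs_scale reflectance scale factor.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scene = list(), rgb = list(),
                            fusion = list(), n_train_plots = 8L,
                            n_test_plots = 4L, crown_split_fraction = 0.8,
                            bad_band_windows = default_bad_band_windows(),
                            n_bins = 39L, max_height = 40,
                            lower_percentile = 1, upper_percentile = 99,
                            threshold = 0.5, other_mass = 0.5,
                            hs_scale = 10000) {
  scene$seed <- scene$seed %||% seed
  rgb$seed <- rgb$seed %||% (seed + 1L)
  fusion$seed <- fusion$seed %||% (seed + 2L)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scene = do.call(scene_config, scene),
                 rgb = do.call(rgb_train_config, rgb),
                 fusion = do.call(fusion_config, fusion),
                 n_train_plots = as.integer(n_train_plots),
                 n_test_plots = as.integer(n_test_plots),
                 crown_split_fraction = crown_split_fraction,
                 bad_band_windows = bad_band_windows,
                 n_bins = as.integer(n_bins), max_height = max_height,
                 lower_percentile = lower_percentile,
                 upper_percentile = upper_percentile,
                 threshold = threshold, other_mass = other_mass,
                 hs_scale = hs_scale),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the arguments of [pipeline_config()]; `scene`, `rgb`
#' and `fusion` are nested mappings.
#'
#' @param path YAML file.
#' @param out_dir optional override of the configured run directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  if (!is.null(y$bad_band_windows)) {
    y$bad_band_windows <- lapply(y$bad_band_windows, as.numeric)
  }
  do.call(pipeline_config, y)
}

## ---- stage caching --------------------------------------------------------

config_digest <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, sprintf(".stage_%s.json", stage))
}

stage_up_to_date <- function(out_dir, stage, input_files, config_obj, output_files) {
  mp <- stage_manifest_path(out_dir, stage)
  if (!file.exists(mp) || !all(file.exists(output_files))) return(FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  cur <- list(inputs = unname(tools::md5sum(input_files[file.exists(input_files)])),
              config = config_digest(config_obj))
  identical(as.character(man$inputs), as.character(cur$inputs)) &&
    identical(man$config, cur$config)
}

record_stage <- function(out_dir, stage, input_files, config_obj) {
  jsonlite::write_json(
    list(inputs = unname(tools::md5sum(input_files[file.exists(input_files)])),
         config = config_digest(config_obj)),
    stage_manifest_path(out_dir, stage), auto_unbox = TRUE)
}

## ---- stages ---------------------------------------------------------------

#' Synthesize the train/test scene set for a run
#'
#' Writes `train/` and `test/` scene directories under the run directory
#' (test labels withheld to `test/labels_withheld.csv`). A no-op when the
#' configuration is unchanged and the outputs exist.
#'
#' @param config a [pipeline_config()].
#' @return run directory, invisibly.
#' @export
run_synthesize <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(config$out_dir, c("train/field.csv", "test/field.csv",
                                         "test/labels_withheld.csv"))
  cfg_obj <- config[c("scene", "n_train_plots", "n_test_plots")]
  if (stage_up_to_date(config$out_dir, "synthesize", character(), cfg_obj, outputs)) {
    message("synthesize: up to date, skipping")
    return(invisible(config$out_dir))
  }
  make_scene_set(config$scene, config$out_dir,
                 n_train_plots = config$n_train_plots,
                 n_test_plots = config$n_test_plots)
  record_stage(config$out_dir, "synthesize", character(), cfg_obj)
  invisible(config$out_dir)
}

# Load one scene directory: crown records plus per-plot rasters and
# anomaly-filtered point clouds.
load_scene <- function(dir, config) {
  crowns <- load_crowns(file.path(dir, "crowns.geojson"),
                        file.path(dir, "field.csv"))
  plots <- unique(crowns$plot_id)
  data <- lapply(plots, function(p) {
    pts <- read_xyz(file.path(dir, sprintf("points_%s.xyz", p)))
    list(rgb = read_raster_tile(file.path(dir, sprintf("rgb_%s.tif", p))),
         hs = read_raster_tile(file.path(dir, sprintf("hs_%s.csv", p))),
         points = filter_height_anomalies(pts, config$lower_percentile,
                                          config$upper_percentile))
  })
  names(data) <- plots
  list(crowns = crowns, plots = data)
}

# Crown chips (raw clipped RGB) for a loaded scene.
scene_chips <- function(scene) {
  lapply(seq_len(nrow(scene$crowns)), function(i) {
    r <- scene$crowns[i, ]
    bb <- c(r$xmin, r$ymin, r$xmax, r$ymax)
    list(values = clip_raster(scene$plots[[r$plot_id]]$rgb, bb)$values,
         individual_id = r$individual_id, label = r$taxon_code)
  })
}

#' Extract fusion features for every crown of a scene directory
#'
#' Runs the three per-crown extractions (RGB class probabilities through the
#' supplied model, centroid reflectance with bad bands removed, lidar
#' pseudo-waveform features) and assembles the fusion feature matrix.
#'
#' @param scene_dir scene directory (from [run_synthesize()] or external
#'   data laid out the same way).
#' @param rgb_model a fitted `rgb_model`.
#' @param config a [pipeline_config()].
#' @return list with `features` (matrix, rownames = individual ids),
#'   `crowns` (records) and `feature_config`.
#' @export
extract_fusion_features <- function(scene_dir, rgb_model, config) {
  scene <- load_scene(scene_dir, config)
  k <- length(rgb_model$classes)
  n_good <- NULL
  feats <- lapply(seq_len(nrow(scene$crowns)), function(i) {
    r <- scene$crowns[i, ]
    bb <- c(r$xmin, r$ymin, r$xmax, r$ymax)
    pl <- scene$plots[[r$plot_id]]
    chip <- clip_raster(pl$rgb, bb)$values
    probs <- predict_rgb_probs(rgb_model, chip)
    spec <- extract_crown_spectrum(pl$hs, bb, scale_factor = config$hs_scale)
    good <- apply_bad_bands(spec, windows = config$bad_band_windows)$values
    wf <- compute_pseudowaveform(pl$points, bb, n_bins = config$n_bins,
                                 max_height = config$max_height)
    if (is.null(n_good)) n_good <<- length(good)
    assemble_features(probs, good, waveform_features(wf),
                      fusion_feature_config(k, length(good), config$n_bins + 1L))
  })
  features <- do.call(rbind, feats)
  rownames(features) <- scene$crowns$individual_id
  list(features = features, crowns = scene$crowns,
       feature_config = fusion_feature_config(k, n_good, config$n_bins + 1L))
}

#' Write a submission table of augmented taxon probabilities
#'
#' One row per test crown: `individual_id`, one probability column per
#' taxon code, and `Other`; each row sums to 1.
#'
#' @param probs augmented probability matrix with named columns and
#'   rownames = individual ids.
#' @param path output CSV.
#' @export
write_submission <- function(probs, path) {
  df <- data.frame(individual_id = rownames(probs), probs, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline end to end
#'
#' Synthesizes (or reuses) the scene set, trains the RGB classifier on the
#' training crowns, extracts and fuses features, trains the fusion network,
#' predicts the test crowns, applies the open-set post-processing, writes
#' the submission CSV, and scores it against the withheld test labels
#' (out-of-training taxa grouped as "Other").
#'
#' @param config a [pipeline_config()].
#' @return list with `submission` (augmented probability matrix), `report`
#'   (a [score_report()]), `rgb_model`, `fusion_model` and file paths.
#' @export
run_end_to_end <- function(config) {
  run_synthesize(config)
  train_dir <- file.path(config$out_dir, "train")
  test_dir <- file.path(config$out_dir, "test")

  train_scene <- load_scene(train_dir, config)
  rgb_model <- fit_rgb_classifier(scene_chips(train_scene), config$rgb)

  train_feat <- extract_fusion_features(train_dir, rgb_model, config)
  fusion_model <- train_fusion(train_feat$features, train_feat$crowns$taxon_code,
                               config$fusion)

  test_feat <- extract_fusion_features(test_dir, rgb_model, config)
  probs <- predict_taxa(fusion_model, test_feat$features)
  aug <- apply_other_threshold(probs, threshold = config$threshold,
                               other_mass = config$other_mass)
  rownames(aug) <- rownames(test_feat$features)
  sub_path <- file.path(config$out_dir, "submission.csv")
  write_submission(aug, sub_path)

  truth <- utils::read.csv(file.path(test_dir, "labels_withheld.csv"),
                           stringsAsFactors = FALSE)
  truth_codes <- truth$taxon_code[match(rownames(aug), truth$individual_id)]
  report <- score_report(truth_codes, aug,
                         class_order = colnames(aug))
  write_score_report(report, file.path(config$out_dir, "score_report"))

  list(submission = aug, report = report, rgb_model = rgb_model,
       fusion_model = fusion_model,
       paths = list(submission = sub_path,
                    report = file.path(config$out_dir, "score_report.csv")))
}
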