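#' Experiment configuration
#'
#' Bundles everything a full pipeline run needs: the scene generator
#' configuration, the detector/segmenter noise model, the forest
#' hyperparameters (or a tuning grid), the confidence thresholds of the
#' sweep, the number of scenes, the positive fraction, the master seed and
#' the output directory. All randomness flows from `seed`; re-running the
#' same configuration reproduces every numeric output byte for byte.
#'
#' @param scene a [scene_config()].
#' @param noise a [noise_config()].
#' @param forest a [forest_params()], or a list of them to trigger a
#'   [grid_search()] on the training split.
#' @param thresholds confidence thresholds for the sweep (sorted
#'   ascending).
#' @param n_scenes number of scenes to simulate.
#' @param prop_positive fraction of scenes carrying a lesion.
#' @param seed master integer seed.
#' @param outdir output directory for artifacts.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(scene = scene_config(), noise = noise_config(),
                              forest = forest_params(),
                              thresholds = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              n_scenes = 200L, prop_positive = 0.85,
                              seed = 1L, outdir = tempfile("cystdx_run_")) {
  stopifnot(n_scenes >= 10, prop_positive > 0, prop_positive <= 1)
  thresholds <- sort(thresholds)
  structure(list(scene = scene, noise = noise, forest = forest,
                 thresholds = thresholds, n_scenes = as.integer(n_scenes),
                 prop_positive = prop_positive, seed = as.integer(seed),
                 outdir = outdir),
            class = "experiment_config")
}

# Polynomial rolling hash of a config's deparsed form; manifest fingerprint.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)[setdiff(names(unclass(config)),
                                                           "outdir")]),
                           collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Executes every stage end to end: scene simulation, detector and
#' segmenter simulation, overlap feature extraction in both branches
#' (features from the annotated ground-truth box and from the
#' highest-confidence detected box, both overlaid on the degraded
#' "predicted" masks), an 80/20 stratified split, Random Forest training
#' (optionally grid-search tuned), detection metrics over the IoU range,
#' the image-level confidence sweep, the classification threshold sweep
#' with sample attrition, and a per-structure Dice report. All artifacts
#' are written under `config$outdir` together with a manifest.
#'
#' Scenes are processed in a stream (masks are dropped once features and
#' Dice contributions are extracted), so memory stays flat in the number
#' of scenes.
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a list with `manifest`, `features_annotated`,
#'   `features_predicted`, `model`, `detection_metrics`, `image_sweep`,
#'   `annotated_report`, `sweep`, `dice_report`, `split`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 5L)
  n <- config$n_scenes
  scene_seeds <- derive_seeds(seeds[1], n)
  det_seeds <- derive_seeds(seeds[2], n)
  mask_seeds <- derive_seeds(seeds[3], n)
  n_pos <- as.integer(round(n * config$prop_positive))
  neg_config <- config$scene
  neg_config$n_lesions <- 0L

  ann_rows <- list(); pred_rows <- list()
  det_dataset <- vector("list", n)
  scene_stubs <- vector("list", n)
  det_lists <- vector("list", n)
  dice_acc <- list()
  annotation_lines <- paste(c("scene_id", "x", "y", "w", "h", "age", "sex",
                              "diagnosis"), collapse = "\t")

  for (i in seq_len(n)) {
    cfg <- if (i <= n_pos) config$scene else neg_config
    scene <- generate_scene(cfg, scene_seeds[i],
                            scene_id = sprintf("scene_%06d", i))
    dets <- simulate_detections(scene, config$noise, det_seeds[i])
    pred_masks <- degrade_mask_set(scene, config$noise, mask_seeds[i])
    for (key in names(scene$masks)) {
      if (sum(scene$masks[[key]]) == 0 && sum(pred_masks[[key]]) == 0) next
      dice_acc[[key]] <- c(dice_acc[[key]],
                           dice(pred_masks[[key]], scene$masks[[key]]))
    }
    for (lesion in scene$lesions) {
      b <- lesion$box
      annotation_lines <- c(annotation_lines,
                            paste(c(scene$scene_id, b$x, b$y, b$w, b$h,
                                    scene$demographics$age,
                                    scene$demographics$sex, lesion$class),
                                  collapse = "\t"))
    }
    det_dataset[[i]] <- list(
      detections = dets,
      ground_truths = lapply(scene$lesions, `[[`, "box"))
    scene_stubs[[i]] <- list(scene_id = scene$scene_id, width = scene$width,
                             height = scene$height, lesions = scene$lesions)
    det_lists[[i]] <- dets
    if (length(scene$lesions) > 0) {
      label <- scene$lesions[[1]]$class
      ann_rows[[length(ann_rows) + 1L]] <-
        list(box = scene$lesions[[1]]$box, masks = pred_masks,
             sample_id = scene$scene_id, source = "annotated_box",
             label = label, confidence = NA_real_)
      top <- select_top_box(dets, 0)
      if (!is.null(top)) {
        pred_rows[[length(pred_rows) + 1L]] <-
          list(box = top$box, masks = pred_masks, sample_id = scene$scene_id,
               source = "predicted_box", label = label,
               confidence = top$confidence)
      }
    }
  }

  feats_ann <- feature_table(ann_rows)
  feats_pred <- if (length(pred_rows) > 0) feature_table(pred_rows) else NULL

  split <- split_80_20(feats_ann$label, seed = seeds[4])
  X_tr <- feature_matrix(feats_ann[split$train, ])
  y_tr <- feats_ann$label[split$train]
  tuning <- NULL
  params <- config$forest
  if (!inherits(params, "forest_params")) {
    tuning <- grid_search(X_tr, y_tr, params, seed = seeds[5])
    params <- tuning$best
  }
  model <- fit_forest(X_tr, y_tr, params, seed = seeds[5])

  test_ids <- feats_ann$sample_id[split$test]
  X_te <- feature_matrix(feats_ann[split$test, ])
  y_te <- feats_ann$label[split$test]
  ann_report <- two_class_report(y_te, predict(model, X_te)$label)

  sweep <- threshold_sweep(feats_pred, model, config$thresholds,
                           sample_ids = test_ids)

  detection_metrics <- ap_ar_over_range(det_dataset)
  has_negative <- n_pos < n
  img_sweep <- if (has_negative) {
    image_level_sweep(det_dataset, config$thresholds)
  } else NULL
  dice_rep <- vapply(dice_acc, mean, numeric(1))

  manifest <- list(package = "cystdx",
                   version = as.character(utils::packageVersion("cystdx")),
                   config_hash = config_hash(config),
                   seed = config$seed,
                   stage_seeds = as.integer(seeds),
                   n_scenes = n, n_positive = n_pos,
                   n_classified_samples = nrow(feats_ann),
                   forest = unclass(params),
                   thresholds = config$thresholds)

  out <- config$outdir
  writeLines(annotation_lines, file.path(out, "annotations.tsv"))
  write_coco_json(scene_stubs, file.path(out, "coco_ground_truth.json"))
  write_coco_json(scene_stubs, file.path(out, "coco_detections.json"),
                  detections = det_lists)
  utils::write.csv(feats_ann, file.path(out, "features_annotated.csv"),
                   row.names = FALSE)
  if (!is.null(feats_pred)) {
    utils::write.csv(feats_pred, file.path(out, "features_predicted.csv"),
                     row.names = FALSE)
  }
  save_forest(model, file.path(out, "model.json"))
  utils::write.csv(data.frame(iou = names(detection_metrics$ap_at_iou),
                              ap = detection_metrics$ap_at_iou,
                              ar = detection_metrics$ar_at_iou,
                              row.names = NULL),
                   file.path(out, "detection_metrics.csv"), row.names = FALSE)
  if (!is.null(img_sweep)) {
    utils::write.csv(img_sweep, file.path(out, "image_level_sweep.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(report_as_df(ann_report),
                   file.path(out, "annotated_report.csv"), row.names = FALSE)
  utils::write.csv(sweep, file.path(out, "threshold_sweep.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(structure = names(dice_rep),
                              mean_dice = dice_rep, row.names = NULL),
                   file.path(out, "dice_report.csv"), row.names = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, features_annotated = feats_ann,
                 features_predicted = feats_pred, model = model,
                 detection_metrics = detection_metrics,
                 image_sweep = img_sweep, annotated_report = ann_report,
                 sweep = sweep, dice_report = dice_rep, split = split,
                 tuning = tuning))
}

#' Classification sweep over detector confidence thresholds
#'
#' For each threshold `t`, keeps the samples whose chosen detection box
#' has confidence `>= t` (samples without such a box are removed — this
#' is the sample attrition that makes the retained count non-increasing
#' in `t`), classifies the retained feature vectors with the forest and
#' reports per-class diagnostic metrics. A threshold retaining no samples
#' or a single truth class yields a flagged (all-`NA`) row.
#'
#' @param features predicted-box feature table from [feature_table()]
#'   (with `label` and `confidence` columns), or `NULL`.
#' @param model a fitted `cyst_forest`.
#' @param thresholds confidence thresholds.
#' @param sample_ids optional subset of `sample_id` values to evaluate
#'   (e.g. the held-out test scenes).
#' @return Data frame with one row per threshold: `threshold`,
#'   `n_samples_retained`, and per-class sensitivity/specificity/PPV/NPV/
#'   F1 columns prefixed `odontogenic_` / `non_odontogenic_`.
#' @export
threshold_sweep <- function(features, model, thresholds,
                            sample_ids = NULL) {
  thresholds <- sort(thresholds)
  empty_row <- function(t, n_kept) {
    row <- data.frame(threshold = t, n_samples_retained = n_kept)
    for (cl in cyst_classes()) {
      for (m in c("sensitivity", "specificity", "ppv", "npv", "f1")) {
        row[[paste0(cl, "_", m)]] <- NA_real_
      }
    }
    row
  }
  if (!is.null(features) && !is.null(sample_ids)) {
    features <- features[features$sample_id %in% sample_ids, , drop = FALSE]
  }
  rows <- lapply(thresholds, function(t) {
    if (is.null(features) || nrow(features) == 0) return(empty_row(t, 0L))
    kept <- features[features$confidence >= t, , drop = FALSE]
    if (nrow(kept) == 0 || length(unique(kept$label)) < 2) {
      return(empty_row(t, nrow(kept)))
    }
    pred <- predict(model, feature_matrix(kept))$label
    rep <- two_class_report(kept$label, pred)
    row <- data.frame(threshold = t, n_samples_retained = nrow(kept))
    for (cl in cyst_classes()) {
      m <- rep[[cl]]
      row[[paste0(cl, "_sensitivity")]] <- m$sensitivity
      row[[paste0(cl, "_specificity")]] <- m$specificity
      row[[paste0(cl, "_ppv")]] <- m$ppv
      row[[paste0(cl, "_npv")]] <- m$npv
      row[[paste0(cl, "_f1")]] <- m$f1
    }
    row
  })
  do.call(rbind, rows)
}
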