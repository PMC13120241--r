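#' Pipeline run configuration
#'
#' Bundles every stage's parameters: the simulation config, the feature
#' set, the environmental-correction mode, the cross-validation scheme,
#' the model list, the fusion strategies and the seeds. Defaults mirror
#' the study conditions: 10 stratified folds, 5-day blocks for the
#' leave-k-day-out scheme, a 0.8 detection confidence threshold, EWMA
#' alphas `{0.1, 0.01, 0.001}`.
#'
#' @param sim a [sim_config()].
#' @param feature_set `"large"` (85 features) or `"small"` (10).
#' @param correction `"off"`, `"features"` or `"response"`; see
#'   [feature_table()].
#' @param cv_scheme,k,block_days cross-validation plan parameters; see
#'   [make_cv_plan()].
#' @param models classifier names for [run_suite()].
#' @param n_repeats repeated seeded runs per model and fold.
#' @param fusion_strategies subset of `"max_confidence"`, `"majority"`.
#' @param conf_threshold,iou_threshold image-side thresholds; see
#'   [image_label()].
#' @param seed master seed for CV shuffles and model initialisations.
#' @param out_dir optional directory; when given, [run_pipeline()] writes
#'   the feature table, prediction CSVs, metrics JSON, fusion report and a
#'   manifest of the resolved configuration there.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            feature_set = c("large", "small"),
                            correction = c("off", "features", "response"),
                            cv_scheme = "stratified_kfold", k = 10,
                            block_days = 5,
                            models = c("lr", "rf", "elm"),
                            n_repeats = 1,
                            fusion_strategies = c("max_confidence", "majority"),
                            conf_threshold = 0.8, iou_threshold = 0.5,
                            seed = 1, out_dir = NULL) {
  structure(
    list(sim = sim, feature_set = match.arg(feature_set),
         correction = match.arg(correction), cv_scheme = cv_scheme, k = k,
         block_days = block_days, models = models, n_repeats = n_repeats,
         fusion_strategies = fusion_strategies,
         conf_threshold = conf_threshold, iou_threshold = iou_threshold,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the end-to-end pipeline
#'
#' simulate -> segment -> extract features (optionally environment-
#' corrected) -> cross-validated classifier suite -> image-side
#' detection-to-label reduction -> decision fusion and agreement analysis.
#' The whole bundle is a pure function of the configuration (all seeds are
#' explicit), so identical configs reproduce identical reports.
#'
#' @param config a [pipeline_config()].
#' @param dataset optionally, a pre-simulated dataset (to reuse across
#'   modes); defaults to `simulate_dataset(config$sim)`.
#' @return list of class `run_bundle`: `dataset`, `features`, `suite`,
#'   `image_predictions`, `fusion` (one `fusion_result` per model), and
#'   the resolved `config`.
#' @export
run_pipeline <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(dataset)) dataset <- simulate_dataset(config$sim)
  features <- feature_table(dataset, config$feature_set, config$correction)
  plan <- make_cv_plan(dataset$metadata, config$cv_scheme, k = config$k,
                       block_days = config$block_days, seed = config$seed)
  suite <- run_suite(features, dataset$labels, plan, models = config$models,
                     n_repeats = config$n_repeats, base_seed = config$seed)
  image_preds <- do.call(rbind, lapply(seq_along(dataset$detections), function(i) {
    image_label(dataset$detections[[i]], config$conf_threshold,
                config$iou_threshold, dataset$metadata$sample_id[i])
  }))
  fusion <- lapply(config$models, function(m) {
    op <- suite_predictions(suite, m)
    op <- op[match(dataset$metadata$sample_id, op$sample_id), ]
    fusion_report(op, image_preds, dataset$labels,
                  strategies = config$fusion_strategies)
  })
  names(fusion) <- config$models
  bundle <- structure(
    list(dataset = dataset, features = features, suite = suite,
         image_predictions = image_preds, fusion = fusion, config = config),
    class = "run_bundle"
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(bundle$features),
                              bundle$features, check.names = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(bundle$suite$predictions,
                   file.path(dir, "odour_predictions.csv"), row.names = FALSE)
  utils::write.csv(bundle$image_predictions,
                   file.path(dir, "image_predictions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(metrics = bundle$suite$metrics,
         fusion = lapply(bundle$fusion, function(f) {
           list(table = f$table, agreement = f$agreement)
         })),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA
  )
  cfg <- bundle$config
  cfg$sim$surfaces <- if (is.null(cfg$sim$surfaces)) NULL else "<correction surfaces>"
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  # agreed samples: the pseudolabeling surface
  first <- bundle$fusion[[1]]
  od <- suite_predictions(bundle$suite, bundle$config$models[1])
  od <- od[match(bundle$dataset$metadata$sample_id, od$sample_id), ]
  agree <- bundle$image_predictions$available & od$label == bundle$image_predictions$label
  agree[is.na(agree)] <- FALSE
  utils::write.csv(
    data.frame(sample_id = bundle$dataset$metadata$sample_id[agree],
               agreed_label = od$label[agree]),
    file.path(dir, "agreed_samples.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' @export
print.run_bundle <- function(x, ...) {
  print(x$dataset)
  print(x$suite)
  for (m in names(x$fusion)) {
    cat("fusion with odour model", m, ":\n")
    print(x$fusion[[m]])
  }
  invisible(x)
}

#' Ablation over environmental-correction modes
#'
#' Runs the suite once per correction mode on the same simulated dataset,
#' with the same folds and seeds (a paired comparison), and tabulates the
#' mean accuracy per mode and model.
#'
#' @param config a [pipeline_config()]; its `correction` entry is ignored.
#' @param modes at least two of `"off"`, `"features"`, `"response"`.
#' @param dataset optional pre-simulated dataset.
#' @return data.frame with one row per mode and model.
#' @export
compare_modes <- function(config, modes = c("off", "features", "response"),
                          dataset = NULL) {
  stopifnot(inherits(config, "run_config"), length(modes) >= 2)
  modes <- match.arg(modes, c("off", "features", "response"), several.ok = TRUE)
  if (is.null(dataset)) dataset <- simulate_dataset(config$sim)
  plan <- make_cv_plan(dataset$metadata, config$cv_scheme, k = config$k,
                       block_days = config$block_days, seed = config$seed)
  out <- lapply(modes, function(mode) {
    features <- feature_table(dataset, config$feature_set, mode)
    suite <- run_suite(features, dataset$labels, plan, models = config$models,
                       n_repeats = config$n_repeats, base_seed = config$seed)
    data.frame(mode = mode, suite$metrics[, c("model", "accuracy_mean",
                                              "accuracy_sd", "f1_mean")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
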