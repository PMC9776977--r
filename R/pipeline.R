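# End-to-end orchestration of the two experiments: csPCa (GG >= 3)
# prediction and the Gleason-group similarity analysis.

#' Build a pipeline run configuration
#'
#' @param cohort a [cohort_spec()] to simulate, a cohort directory path (as
#'   written by [write_cohort()]), or an `adc_cohort`.
#' @param window_size,min_support,n_bins local-map parameters.
#' @param selection_folds,selection_alpha,selection_weighting,max_screened
#'   feature-selection settings (see [select_features()]).
#' @param augmentation enable feature-space augmentation; `FALSE` is the
#'   "preliminary model" pathway trained on the original lesions only.
#' @param augment_method,n_target see [augment()].
#' @param augment_order `"split_first"` (default: the original lesions are
#'   split, then each pool is augmented independently, avoiding synthetic
#'   leakage across the split) or `"augment_first"` (oversample to
#'   `n_target`, then split).
#' @param split_rule,train_frac see [split_augmented()].
#' @param svm an [svm_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir artifact directory (created); `NULL` runs in memory only.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), window_size = 9,
                       min_support = 0.5, n_bins = 32, selection_folds = 10,
                       selection_alpha = 1e-3,
                       selection_weighting = "balanced", max_screened = 17,
                       augmentation = TRUE,
                       augment_method = "interpolate", n_target = 200,
                       augment_order = c("split_first", "augment_first"),
                       split_rule = "random", train_frac = 0.75,
                       svm = svm_config(), seed = 1, out_dir = NULL) {
  structure(list(cohort = cohort, window_size = window_size,
                 min_support = min_support, n_bins = n_bins,
                 selection_folds = selection_folds,
                 selection_alpha = selection_alpha,
                 selection_weighting = selection_weighting,
                 max_screened = max_screened, augmentation = augmentation,
                 augment_method = augment_method, n_target = n_target,
                 augment_order = match.arg(augment_order),
                 split_rule = split_rule, train_frac = train_frac,
                 svm = svm, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments;
#'   `cohort` may be a directory path or a map of [cohort_spec()] keys, and
#'   `svm` a map of [svm_config()] keys.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort) && is.list(y$cohort)) {
    y$cohort <- do.call(cohort_spec, y$cohort)
  }
  if (!is.null(y$svm)) y$svm <- do.call(svm_config, y$svm)
  do.call(run_config, y)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  .adc_log("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full pipeline
#'
#' Feature extraction, two-stage selection, Gleason-group similarity
#' analysis on the signature decision values, augmentation and stratified
#' split, SVM signature training with calibration, and train/test metric
#' reports. With `out_dir` set, all artifacts (feature table, selection,
#' model, reports, figures) are written together with a JSON manifest
#' holding their MD5 hashes and the seeds used.
#'
#' @param config a [run_config()].
#' @return list with `feature_table`, `selection`, `similarity`, `split`,
#'   `model`, `metrics_train`, `metrics_test`, `augmented` and `manifest`.
#' @export
run_full <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- .stage("cohort", {
    if (inherits(config$cohort, "adc_cohort")) config$cohort
    else if (is.character(config$cohort)) read_cohort(config$cohort)
    else generate_cohort(config$cohort)
  })
  table <- .stage("features", build_feature_table(
    cohort, window_size = config$window_size,
    min_support = config$min_support, n_bins = config$n_bins))
  selection <- .stage("selection", select_features(
    table, folds = config$selection_folds, seed = seed + 1L,
    weighting = config$selection_weighting, alpha = config$selection_alpha,
    max_screened = config$max_screened))
  norm <- minmax_normalize(table, params = selection$normalization)
  chosen <- selection$result$chosen
  x4 <- norm$x[, chosen, drop = FALSE]
  y <- table$cspca
  similarity <- .stage("similarity", {
    sig_svm <- svm_linear_fit(x4, y)
    scores <- predict(sig_svm, x4)
    list(report = gg_similarity_report(scores, table$gg), scores = scores)
  })
  split <- .stage("split", {
    if (!config$augmentation) {
      set.seed(seed + 3L)
      split_augmented(list(x = x4, labels = y), train_frac = config$train_frac,
                      rule = config$split_rule, seed = seed + 3L)
    } else if (config$augment_order == "augment_first") {
      aug <- augment(x4, y, n_target = config$n_target, seed = seed + 2L,
                     method = config$augment_method)
      split_augmented(aug, train_frac = config$train_frac,
                      rule = config$split_rule, seed = seed + 3L)
    } else {
      pre <- suppressWarnings(split_augmented(
        list(x = x4, labels = y), train_frac = config$train_frac,
        rule = "random", seed = seed + 3L))
      n_train <- round(config$n_target * config$train_frac / 2) * 2
      aug_tr <- augment(pre$train$x, pre$train$labels, n_target = n_train,
                        seed = seed + 2L, method = config$augment_method)
      aug_te <- augment(pre$test$x, pre$test$labels,
                        n_target = config$n_target - n_train,
                        seed = seed + 4L, method = config$augment_method)
      structure(list(train = list(x = aug_tr$x, labels = aug_tr$labels,
                                  idx = NA),
                     test = list(x = aug_te$x, labels = aug_te$labels,
                                 idx = NA),
                     rule = config$split_rule, seed = seed + 3L,
                     train_frac = config$train_frac),
                class = "split_set")
    }
  })
  cfg_svm <- config$svm
  cfg_svm$seed <- seed + 5L
  model <- .stage("train", train_signature(split, cfg_svm,
                                           feature_names = chosen))
  metrics_train <- .stage("eval-train", evaluate_signature(
    model, split$train$x, split$train$labels, seed = seed + 6L))
  metrics_test <- .stage("eval-test", evaluate_signature(
    model, split$test$x, split$test$labels, seed = seed + 7L))
  out <- list(feature_table = table, selection = selection,
              similarity = similarity$report,
              similarity_scores = similarity$scores, split = split,
              model = model, metrics_train = metrics_train,
              metrics_test = metrics_test, config = config)
  if (!is.null(config$out_dir)) {
    out$manifest <- .write_artifacts(out, config$out_dir)
  }
  out
}

.write_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(name) file.path(dir, name)
  write_feature_table(run$feature_table, f("feature_table.csv"))
  write_selection(run$selection, f("selection.json"))
  write_signature_model(run$model, f("model.json"),
                        normalization = run$selection$normalization)
  sim <- run$similarity
  jsonlite::write_json(
    list(summaries = sim$summaries, omnibus = as.list(sim$omnibus),
         pairwise_location = as.list(sim$pairwise_location),
         pairwise_dispersion = as.list(sim$pairwise_dispersion),
         alpha_location = sim$alpha_location,
         alpha_dispersion = sim$alpha_dispersion),
    f("similarity.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(.metrics_json(run$metrics_train),
                       f("metrics_train.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(.metrics_json(run$metrics_test),
                       f("metrics_test.json"), auto_unbox = TRUE, digits = NA)
  gg <- run$feature_table$gg
  gg_similarity_boxplot(run$similarity_scores, gg, f("boxplot_gg.png"))
  roc_plot(run$metrics_train, f("roc_train.png"))
  roc_plot(run$metrics_test, f("roc_test.png"))
  waterfall_plot(run$metrics_train$waterfall$score,
                 run$metrics_train$waterfall$label, f("waterfall_train.png"))
  waterfall_plot(run$metrics_test$waterfall$score,
                 run$metrics_test$waterfall$label, f("waterfall_test.png"))
  files <- c("feature_table.csv", "feature_table.csv.json", "selection.json",
             "selection.json.combos.csv", "model.json", "similarity.json",
             "metrics_train.json", "metrics_test.json", "boxplot_gg.png",
             "roc_train.png", "roc_test.png", "waterfall_train.png",
             "waterfall_test.png")
  manifest <- list(
    artifacts = lapply(setNames(files, files), function(x) {
      list(md5 = unname(tools::md5sum(file.path(dir, x))))
    }),
    seed = run$config$seed,
    augmentation = run$config$augmentation,
    mode = if (run$config$augmentation) "augmented"
      else "preliminary model without any feature sample augmentation",
    window_size = run$config$window_size,
    chosen_features = run$selection$result$chosen)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
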