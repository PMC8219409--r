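#' Full pipeline configuration
#'
#' Collects every tunable of the end-to-end run. All randomness flows from
#' the single root `seed`, split per stage by fixed labels, so one value
#' reproduces the whole run.
#'
#' @param seed Root integer seed.
#' @param discretize_method,bins Passed to [fit_discretizer()].
#' @param select Run entropy-notion feature selection (default `TRUE`);
#'   `FALSE` trains on all candidate features (ablation).
#' @param select_on_train Restrict selection to the training partition
#'   (leakage-safe variant). The default `FALSE` selects on the full
#'   preprocessed dataset, matching the staged workflow in which feature
#'   selection precedes the train/test split.
#' @param balance_mode `"train-only"` (default: oversample the training
#'   partition after the split, leakage-safe), `"paper"` (oversample the full
#'   dataset before the split, the study's apparent procedure — synthetic
#'   copies then reach the test set) or `"none"`.
#' @param target_fraction,k_neighbors Passed to [balance_config()].
#' @param duplicate Use literal replication instead of SMOTE interpolation.
#' @param train_fraction Passed to [split_spec()] (default 0.70).
#' @param classifiers Subset of `c("DT", "LR", "SVM")` to fit.
#' @param hyperparams Named list of per-classifier hyperparameter lists,
#'   e.g. `list(SVM = list(cost = 2))`.
#' @return An `"rpcm_config"` list.
#' @export
rpcm_config <- function(seed = 42L,
                        discretize_method = "mdl_entropy", bins = 5L,
                        select = TRUE, select_on_train = FALSE,
                        balance_mode = c("train-only", "paper", "none"),
                        target_fraction = 0.5, k_neighbors = 5L,
                        duplicate = FALSE,
                        train_fraction = 0.70,
                        classifiers = c("DT", "LR", "SVM"),
                        hyperparams = list()) {
  balance_mode <- match.arg(balance_mode)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(list(seed = as.integer(seed),
                 discretize_method = discretize_method, bins = as.integer(bins),
                 select = isTRUE(select),
                 select_on_train = isTRUE(select_on_train),
                 balance_mode = balance_mode,
                 target_fraction = target_fraction,
                 k_neighbors = as.integer(k_neighbors),
                 duplicate = isTRUE(duplicate),
                 train_fraction = train_fraction,
                 classifiers = classifiers,
                 hyperparams = hyperparams),
            class = "rpcm_config")
}

#' Run the full risk-prediction pipeline
#'
#' Executes the staged workflow on a cohort: mean/mode imputation,
#' discretization, entropy-notion feature selection, stratified 70/30 split,
#' minority oversampling (per `balance_mode`), training of the configured
#' classifiers and confusion-matrix evaluation on the held-out partition.
#' Every stage's row and feature counts, seeds and the majority-class
#' baseline accuracy are recorded in the returned manifest.
#'
#' @param data A [cohort()] or a path to a cohort CSV.
#' @param config An [rpcm_config()].
#' @param schema Optional schema used when `data` is a path.
#' @return An `"rpcm_result"`: `selection` (a `"selection_result"` or `NULL`),
#'   `reports` (named list of `"evaluation_report"`s), `models`, and
#'   `manifest` (config snapshot, per-stage log, majority baseline, package
#'   version, timestamp).
#' @export
run_rpcm <- function(data, config = rpcm_config(), schema = NULL) {
  stopifnot(inherits(config, "rpcm_config"))
  stage <- function(...) sprintf(...)
  log <- list()
  if (is.character(data)) data <- read_cohort_csv(data, schema = schema)
  assert_cohort(data)
  log$input <- stage("input: %d rows, %d features", nrow(data$data),
                     nrow(data$schema))

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }

  d <- run_stage("impute", impute_missing(data))
  disc <- run_stage("discretize", {
    map <- fit_discretizer(d, method = config$discretize_method,
                           bins = config$bins)
    apply_discretizer(d, map)
  })
  log$preprocess <- stage("preprocess: %d rows, %d candidates",
                          nrow(disc$data), length(candidate_codes(disc)))

  selection <- NULL
  if (config$select && !config$select_on_train) {
    selection <- run_stage("select",
                           select_features(disc, seed = config$seed))
    disc <- cohort_restrict(disc, selection$selected_features)
    log$select <- stage("select: |F0| = %d -> |F| = %d",
                        length(selection$initial_features),
                        length(selection$selected_features))
  }

  bal_cfg <- balance_config(config$target_fraction, config$k_neighbors,
                            seed = config$seed)
  bal_method <- if (config$duplicate) "duplicate" else "smote"
  if (config$balance_mode == "paper") {
    disc <- run_stage("balance", smote_balance(disc, bal_cfg, bal_method))
    log$balance <- stage("balance (paper mode, full dataset): %d rows",
                         nrow(disc$data))
  }

  parts <- run_stage("split", split_dataset(
    disc, split_spec(config$train_fraction, TRUE, seed = config$seed)))
  train <- parts$train
  test <- parts$test
  log$split <- stage("split: %d train / %d test", nrow(train$data),
                     nrow(test$data))

  if (config$select && config$select_on_train) {
    selection <- run_stage("select",
                           select_features(train, seed = config$seed))
    train <- cohort_restrict(train, selection$selected_features)
    test <- cohort_restrict(test, selection$selected_features)
    log$select <- stage("select (train-only): |F0| = %d -> |F| = %d",
                        length(selection$initial_features),
                        length(selection$selected_features))
  }

  if (config$balance_mode == "train-only") {
    train <- run_stage("balance", smote_balance(train, bal_cfg, bal_method))
    log$balance <- stage("balance (train-only): %d train rows",
                         nrow(train$data))
  }

  majority <- as.integer(mean(class_values(train)) > 0.5)
  baseline_acc <- 100 * mean(class_values(test) == majority)

  models <- list()
  reports <- list()
  for (kind in config$classifiers) {
    hp <- config$hyperparams[[kind]] %||% list()
    models[[kind]] <- run_stage(paste0("train-", kind),
                                train_classifier(kind, train, hp))
    reports[[kind]] <- run_stage(paste0("evaluate-", kind),
                                 evaluate(models[[kind]], test))
  }

  manifest <- list(
    config = unclass(config),
    seeds = list(root = config$seed,
                 partition = derive_seed(config$seed, "partition"),
                 split = derive_seed(config$seed, "split"),
                 balance = derive_seed(config$seed, "balance")),
    stages = log,
    majority_baseline_accuracy = baseline_acc,
    version = as.character(utils::packageVersion("ptbrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(selection = selection, reports = reports, models = models,
                 manifest = manifest),
            class = "rpcm_result")
}

#' @export
print.rpcm_result <- function(x, ...) {
  cat("<rpcm_result>\n")
  for (s in x$manifest$stages) cat("  ", s, "\n", sep = "")
  cat(sprintf("  majority baseline accuracy: %.3f%%\n",
              x$manifest$majority_baseline_accuracy))
  cat("\n  Classifier  Accuracy  Sensitivity  Specificity\n")
  for (r in x$reports)
    cat(sprintf("  %-10s  %7.3f%%  %11.3f  %11.3f\n",
                r$kind, r$ccr, r$tpr, r$tnr))
  invisible(x)
}

#' Write pipeline reports to JSON and a Markdown table
#'
#' Metrics are kept at full precision in the JSON report and rounded to three
#' decimals in the Markdown table (accuracy as a proportion alongside the
#' percent-scale CCR).
#'
#' @param result An `"rpcm_result"`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_rpcm_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "rpcm_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(out_dir, "reports.json")
  payload <- list(
    manifest = result$manifest,
    reports = lapply(result$reports, function(r) {
      r <- unclass(r)
      r$undefined <- as.list(r$undefined)
      r
    })
  )
  jsonlite::write_json(payload, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  md_path <- file.path(out_dir, "reports.md")
  lines <- c("| Classifiers | Accuracy | Sensitivity | Specificity |",
             "|---|---|---|---|",
             vapply(result$reports, function(r)
               sprintf("| %s | %.3f | %.3f | %.3f |", r$kind, r$ccr / 100,
                       r$tpr, r$tnr), character(1L)))
  writeLines(lines, md_path)
  paths <- c(report_path, md_path)
  if (!is.null(result$selection)) {
    sel_path <- file.path(out_dir, "selection.json")
    write_selection_result(result$selection, sel_path)
    paths <- c(paths, sel_path)
  }
  invisible(paths)
}
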