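#' Train/test split specification
#'
#' @param train_fraction Proportion of rows assigned to training (default
#'   0.70, giving the 70/30 split used throughout).
#' @param stratified Preserve the class ratio in both partitions (default
#'   `TRUE`).
#' @param seed Integer seed for the assignment.
#' @return A `"split_spec"` list.
#' @export
split_spec <- function(train_fraction = 0.70, stratified = TRUE, seed = 42L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a cohort into training and test partitions
#'
#' The partitions are disjoint and exhaustive, the training partition holds
#' exactly `round(train_fraction * n)` rows, and (when stratified) per-class
#' training counts deviate from the class's proportional share by at most one
#' row. A fixed seed yields an identical assignment across runs.
#'
#' @param data A [cohort()].
#' @param spec A [split_spec()].
#' @return A list with cohorts `train` and `test`.
#' @export
split_dataset <- function(data, spec = split_spec()) {
  assert_cohort(data)
  stopifnot(inherits(spec, "split_spec"))
  y <- class_values(data)
  n <- length(y)
  if (n < 2L) stop("need at least 2 rows to split", call. = FALSE)
  n_train <- round_half_up(spec$train_fraction * n)

  train_idx <- withr::with_seed(derive_seed(spec$seed, "split"), {
    if (spec$stratified) {
      groups <- split(seq_len(n), y)
      if (any(vapply(groups, length, integer(1L)) < 2L))
        stop("stratified split needs at least 2 rows per class",
             call. = FALSE)
      # proportional allocation; remainders to largest fractional parts so
      # the training total is exactly round(train_fraction * n)
      share <- vapply(groups, length, integer(1L)) * spec$train_fraction
      take <- floor(share)
      rem <- n_train - sum(take)
      if (rem > 0) {
        ord <- order(share - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
      } else if (rem < 0) {
        ord <- order(share - take)
        take[ord[seq_len(-rem)]] <- take[ord[seq_len(-rem)]] - 1
      }
      unlist(mapply(function(idx, m) sample(idx)[seq_len(m)],
                    groups, take, SIMPLIFY = FALSE), use.names = FALSE)
    } else {
      sample.int(n, n_train)
    }
  })
  list(train = cohort_rows(data, sort(train_idx)),
       test = cohort_rows(data, sort(setdiff(seq_len(n), train_idx))))
}

#' Train a binary classifier
#'
#' Three interchangeable classifier families are supported, each delegated to
#' its standard implementation:
#'
#' * `DT` — decision tree by recursive partitioning with impurity splitting
#'   ([rpart::rpart()]).
#' * `LR` — binary logistic regression fit by maximum likelihood
#'   ([stats::glm()] with a binomial link); predicted class 1 when the
#'   fitted probability exceeds 0.5.
#' * `SVM` — support vector machine, radial-basis kernel by default
#'   ([e1071::svm()]).
#'
#' Hyperparameters default to the delegate implementations' documented
#' defaults; anything passed via `hyperparams` is forwarded and echoed in the
#' fitted object for reproducibility.
#'
#' @param kind `"DT"`, `"LR"` or `"SVM"`.
#' @param train A [cohort()] containing both classes.
#' @param hyperparams Named list forwarded to the delegate fitter.
#' @return An `"rpcm_model"` exposing `predict(model, newdata)` -> 0/1.
#' @export
train_classifier <- function(kind = c("DT", "LR", "SVM"), train,
                             hyperparams = list()) {
  kind <- match.arg(kind)
  assert_cohort(train)
  y <- class_values(train)
  if (length(unique(y)) < 2L)
    stop("training data contains a single class", call. = FALSE)
  feats <- candidate_codes(train)
  if (!length(feats)) stop("no candidate features to train on", call. = FALSE)
  df <- train$data[, feats, drop = FALSE]
  df$.y <- y

  fit <- switch(kind,
    DT = {
      df$.y <- factor(df$.y, levels = c(0L, 1L))
      do.call(rpart::rpart,
              c(list(formula = .y ~ ., data = df, method = "class"),
                hyperparams))
    },
    LR = do.call(stats::glm,
                 c(list(formula = .y ~ ., data = df, family = stats::binomial()),
                   hyperparams)),
    SVM = {
      df$.y <- factor(df$.y, levels = c(0L, 1L))
      constant <- vapply(df[feats], function(v) length(unique(v)) < 2L,
                         logical(1L))
      args <- c(list(formula = .y ~ ., data = df), hyperparams)
      if (is.null(args$kernel)) args$kernel <- "radial"
      if (any(constant) && is.null(args$scale)) args$scale <- FALSE
      do.call(e1071::svm, args)
    })

  structure(list(kind = kind, fit = fit, features = feats,
                 hyperparams = hyperparams,
                 class_column = train$class_column),
            class = "rpcm_model")
}

#' @export
predict.rpcm_model <- function(object, newdata, ...) {
  df <- if (is_cohort(newdata)) newdata$data else as.data.frame(newdata)
  missing_feats <- setdiff(object$features, names(df))
  if (length(missing_feats))
    stop("newdata lacks feature(s): ", paste(missing_feats, collapse = ", "),
         call. = FALSE)
  df <- df[, object$features, drop = FALSE]
  out <- switch(object$kind,
    DT = as.integer(as.character(predict(object$fit, df, type = "class"))),
    LR = as.integer(predict(object$fit, df, type = "response") > 0.5),
    SVM = as.integer(as.character(predict(object$fit, df))))
  out
}

#' Confusion-matrix performance metrics
#'
#' Computes the standard metric set from the four confusion-matrix counts,
#' with class 1 (preterm birth) as the positive class: correct classification
#' rate `CCR = (TP + TN) / (TP + FP + FN + TN)` reported on the percent
#' scale, sensitivity `TPR = TP / (TP + FN)`, specificity
#' `TNR = TN / (TN + FP)`, `FPR`, `FNR`, `precision = TP / (TP + FP)`,
#' `recall` (= TPR) and `F1 = 2 TP / (2 TP + FP + FN)`. A metric whose
#' denominator is zero is reported as `NA` and named in `undefined`, never
#' silently set to 0.
#'
#' @param tp,fn,fp,tn Nonnegative counts.
#' @return A list of metrics plus `undefined`, a character vector of the
#'   metrics with zero denominators.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0, tp + fn + fp + tn > 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  m <- list(
    ccr = 100 * (tp + tn) / (tp + fn + fp + tn),
    tpr = ratio(tp, tp + fn),
    tnr = ratio(tn, tn + fp),
    fpr = ratio(fp, tn + fp),
    fnr = ratio(fn, tp + fn),
    precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    f1 = ratio(2 * tp, 2 * tp + fp + fn)
  )
  m$undefined <- names(m)[vapply(m, function(v) is.na(v), logical(1L))]
  m
}

#' Evaluate a fitted classifier on a test cohort
#'
#' @param model An `"rpcm_model"` from [train_classifier()].
#' @param test A non-empty [cohort()] whose schema includes every model
#'   feature.
#' @return An `"evaluation_report"`: `kind`, `matrix` (a list with `tp`,
#'   `fn`, `fp`, `tn`) and the [confusion_metrics()] set.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "rpcm_model"))
  assert_cohort(test)
  if (nrow(test$data) == 0L) stop("empty test cohort", call. = FALSE)
  pred <- predict(model, test)
  truth <- class_values(test)
  cm <- list(tp = sum(pred == 1L & truth == 1L),
             fn = sum(pred == 0L & truth == 1L),
             fp = sum(pred == 1L & truth == 0L),
             tn = sum(pred == 0L & truth == 0L))
  metrics <- confusion_metrics(cm$tp, cm$fn, cm$fp, cm$tn)
  structure(c(list(kind = model$kind, matrix = cm), metrics),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s  (tp=%d fn=%d fp=%d tn=%d)\n",
              x$kind, x$matrix$tp, x$matrix$fn, x$matrix$fp, x$matrix$tn))
  cat(sprintf("  accuracy %.3f%%  sensitivity %.3f  specificity %.3f\n",
              x$ccr, x$tpr, x$tnr))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$precision, x$recall, x$f1))
  if (length(x$undefined))
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
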