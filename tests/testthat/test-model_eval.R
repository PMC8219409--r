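test_that("stratified 70/30 split has exact sizes and class balance", {
  y <- rep(c(0L, 1L), each = 50)
  d <- make_cohort(data.frame(GA = sample(0:3, 100, TRUE), PTB = y))
  parts <- split_dataset(d, split_spec(seed = 1))
  expect_equal(nrow(parts$train$data), 70L)
  expect_equal(nrow(parts$test$data), 30L)
  expect_equal(as.integer(table(parts$train$data$PTB)), c(35L, 35L))
  expect_equal(as.integer(table(parts$test$data$PTB)), c(15L, 15L))
})

test_that("split is disjoint, exhaustive, deterministic, and exact on sizes", {
  for (n in c(10L, 40L, 130L)) {
    d <- make_cohort(data.frame(PID = 1:n, GA = rep(0:1, length.out = n),
                                PTB = rep(c(0L, 1L), length.out = n)))
    parts <- split_dataset(d, split_spec(seed = 7))
    expect_equal(nrow(parts$train$data), round(0.7 * n))
    ids <- c(parts$train$data$PID, parts$test$data$PID)
    expect_equal(sort(ids), 1:n)
    again <- split_dataset(d, split_spec(seed = 7))
    expect_identical(again$train$data, parts$train$data)
    if (n > 100L) {
      other <- split_dataset(d, split_spec(seed = 8))
      expect_false(identical(other$train$data$PID, parts$train$data$PID))
    }
  }
})

test_that("a 50/50 split of 2 rows gives one row each (unstratified)", {
  d <- make_cohort(data.frame(GA = c(0L, 1L), PTB = c(0L, 1L)))
  parts <- split_dataset(d, split_spec(0.5, stratified = FALSE, seed = 1))
  expect_equal(nrow(parts$train$data), 1L)
  expect_equal(nrow(parts$test$data), 1L)
  expect_error(split_dataset(d, split_spec(0.5, seed = 1)), "2 rows per class")
})

test_that("all three classifier kinds fit a separable toy set perfectly", {
  y <- rep(c(0L, 1L), each = 20)
  d <- make_cohort(data.frame(GA = y * 3L, BP = 1L - y, PTB = y))
  for (kind in c("DT", "LR", "SVM")) {
    m <- suppressWarnings(train_classifier(kind, d))
    expect_equal(suppressWarnings(predict(m, d)), y)
  }
})

test_that("constant features make every classifier predict the majority", {
  d <- make_cohort(data.frame(GA = rep(1L, 10), PTB = c(rep(0L, 7), rep(1L, 3))))
  for (kind in c("DT", "LR", "SVM")) {
    m <- suppressWarnings(train_classifier(kind, d))
    expect_equal(suppressWarnings(predict(m, d)), rep(0L, 10))
  }
})

test_that("single-class training data and feature mismatch are errors", {
  d <- make_cohort(data.frame(GA = 1:4, PTB = rep(0L, 4)))
  expect_error(train_classifier("DT", d), "single class")

  train <- make_cohort(data.frame(GA = c(0L, 1L, 0L, 1L), PTB = c(0L, 1L, 0L, 1L)))
  m <- train_classifier("DT", train)
  test <- make_cohort(data.frame(BP = c(0L, 1L), PTB = c(0L, 1L)))
  expect_error(evaluate(m, test), "lacks feature")
})

test_that("confusion metrics reproduce hand arithmetic", {
  m <- confusion_metrics(tp = 50, fn = 10, fp = 5, tn = 35)
  expect_equal(m$ccr, 85)
  expect_equal(m$tpr, 0.8333, tolerance = 1e-4)
  expect_equal(m$tnr, 0.8750, tolerance = 1e-4)
  expect_equal(m$precision, 0.9091, tolerance = 1e-4)
  expect_equal(m$f1, 0.8696, tolerance = 1e-4)
  expect_equal(m$recall, m$tpr)
  expect_length(m$undefined, 0L)
})

test_that("perfect predictions give ccr 100 and unit rates", {
  y <- rep(c(0L, 1L), each = 5)
  train <- make_cohort(data.frame(GA = rep(c(0L, 1L), each = 20),
                                  PTB = rep(c(0L, 1L), each = 20)))
  m <- train_classifier("DT", train)
  d <- make_cohort(data.frame(GA = y, PTB = y))
  rep <- evaluate(m, d)
  expect_equal(rep$matrix, list(tp = 5L, fn = 0L, fp = 0L, tn = 5L))
  expect_equal(rep$ccr, 100)
  expect_equal(rep$tpr, 1)
  expect_equal(rep$tnr, 1)
})

test_that("zero-denominator metrics are NA and flagged, never 0", {
  train <- make_cohort(data.frame(GA = c(0L, 0L, 1L, 1L), PTB = c(0L, 0L, 1L, 1L)))
  m <- train_classifier("DT", train)
  allneg <- make_cohort(data.frame(GA = c(0L, 0L), PTB = c(0L, 0L)))
  rep <- evaluate(m, allneg)
  expect_true(is.na(rep$tpr))
  expect_true("tpr" %in% rep$undefined)
  expect_true(is.na(rep$fnr))
  expect_equal(rep$tnr, 1)
})

test_that("metric identities hold on reports from real pipeline runs", {
  gen <- generate_cohort(generator_config(n_rows = 400, seed = 13))
  res <- run_rpcm(gen$cohort, rpcm_config(seed = 13))
  for (r in res$reports) {
    cm <- r$matrix
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    expect_equal(n, 120L)   # 30% of 400
    expect_equal(r$ccr, 100 * (cm$tp + cm$tn) / n)
    expect_equal(r$tpr + r$fnr, 1)
    expect_equal(r$tnr + r$fpr, 1)
    expect_equal(r$f1, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
    expect_equal(r$recall, r$tpr)
  }
})

test_that("the pipeline runs end to end and logs its stages", {
  gen <- generate_cohort(generator_config(n_rows = 400, missing_rate = 0.02,
                                          raw = TRUE, seed = 17))
  res <- run_rpcm(gen$cohort, rpcm_config(seed = 17))
  expect_s3_class(res, "rpcm_result")
  expect_named(res$reports, c("DT", "LR", "SVM"))
  expect_lte(length(res$selection$selected_features), 36L)
  expect_true(all(c("input", "preprocess", "select", "split", "balance") %in%
                  names(res$manifest$stages)))
  expect_true(is.finite(res$manifest$majority_baseline_accuracy))
  # deterministic given the same config
  res2 <- run_rpcm(gen$cohort, rpcm_config(seed = 17))
  expect_equal(res2$reports, res$reports)

  out_dir <- withr::local_tempdir()
  paths <- write_rpcm_reports(res, out_dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(file.path(out_dir, "reports.json"))
  expect_named(js$reports, c("DT", "LR", "SVM"))
})

test_that("disabling selection trains on all candidate features", {
  gen <- generate_cohort(generator_config(n_rows = 300, seed = 19))
  res <- run_rpcm(gen$cohort, rpcm_config(seed = 19, select = FALSE,
                                          classifiers = "DT"))
  expect_null(res$selection)
  expect_equal(res$models$DT$features,
               gen$cohort$schema$code[gen$cohort$schema$role == "candidate"])
})

test_that("classifier accuracy beats the majority baseline on easy cohorts", {
  gen <- generate_cohort(generator_config(n_rows = 600, seed = 23))
  res <- run_rpcm(gen$cohort, rpcm_config(seed = 23))
  for (r in res$reports)
    expect_gt(r$ccr, res$manifest$majority_baseline_accuracy)
})
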