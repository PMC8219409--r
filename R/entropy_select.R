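#' Class entropy of a set of instances
#'
#' Entropy in bits of a class distribution: `-sum(p_m * log2(p_m))` over the
#' classes with nonzero probability (the `0 * log2(0)` term is taken as 0).
#' For a binary problem the entropy is at most 1 bit; in general at most
#' `log2(c)` for `c` classes.
#'
#' @param class_counts Named (or unnamed) vector of nonnegative class counts
#'   with positive total.
#' @return Entropy in bits.
#' @export
#' @examples
#' compute_entropy(c(`0` = 5, `1` = 5))   # 1 bit
#' compute_entropy(c(10, 0))              # 0 bits
compute_entropy <- function(class_counts) {
  if (!is.numeric(class_counts) || any(class_counts < 0))
    stop("class_counts must be nonnegative numbers", call. = FALSE)
  total <- sum(class_counts)
  if (total <= 0) stop("all class counts are zero", call. = FALSE)
  p <- class_counts[class_counts > 0] / total
  -sum(p * log2(p))
}

#' Information gain of one feature
#'
#' `Gain(S, A) = Entropy(S) - sum_j (|S_vj| / |S|) * Entropy(S_vj)`, where
#' the `S_vj` partition the instance set `S` by the observed values `v_j` of
#' feature `A`. The gain of a feature identical to the class equals
#' `Entropy(S)`; a constant feature has gain 0.
#'
#' @param data A [cohort()]; the feature must be fully discrete (no missing
#'   values).
#' @param feature Code of a candidate feature.
#' @return Gain in bits.
#' @export
compute_gain <- function(data, feature) {
  assert_cohort(data)
  i <- match(feature, data$schema$code)
  if (is.na(i)) stop("unknown feature '", feature, "'", call. = FALSE)
  if (data$schema$role[i] != "candidate")
    stop("feature '", feature, "' has role '", data$schema$role[i],
         "'; only candidate features are scored", call. = FALSE)
  x <- data$data[[feature]]
  if (anyNA(x))
    stop("feature '", feature, "' has missing values; impute first",
         call. = FALSE)
  n <- length(x)
  if (length(unique(x)) > max(2L, n / 2))
    warning("feature '", feature, "' looks continuous (",
            length(unique(x)), " distinct values in ", n,
            " rows); discretize before scoring", call. = FALSE)
  gain_xy(x, class_values(data))
}

gain_xy <- function(x, y) {
  hs <- entropy_of(y)
  n <- length(y)
  cond <- 0
  for (v in split(y, x)) cond <- cond + (length(v) / n) * entropy_of(v)
  hs - cond
}

#' Range-based selection threshold
#'
#' `r = (max(gains) - min(gains)) / n`, with `n` the number of candidate
#' features scored. Features whose gain falls strictly below `r` are
#' discarded; `r` is 0 (nothing discarded) when all gains tie.
#'
#' @param gains Named numeric vector of per-feature gains.
#' @return The threshold `r`, in bits.
#' @export
compute_threshold <- function(gains) {
  if (!length(gains)) stop("no gains supplied", call. = FALSE)
  (max(gains) - min(gains)) / length(gains)
}

#' Select features within one data subset
#'
#' Scores every feature of `initial` by information gain on `data_subset`,
#' computes the range threshold `r`, and keeps the features with gain `>= r`
#' (removal requires strictly smaller gain, so ties with the threshold are
#' kept). On a single-class subset all gains are 0, `r` is 0, every feature
#' is kept and a warning is emitted.
#'
#' @param data_subset A discrete, fully observed [cohort()].
#' @param initial Character vector of candidate feature codes (`F0`).
#' @param subset_id Integer tag stored in the report.
#' @return A list with `features` (the kept subset, in `initial` order) and
#'   `report`, a `"gain_report"`: `subset_id`, `dataset_entropy`, `gains`,
#'   `threshold`, `n_candidates`.
#' @export
select_subset <- function(data_subset, initial, subset_id = 1L) {
  assert_cohort(data_subset)
  if (nrow(data_subset$data) == 0L) stop("empty data subset", call. = FALSE)
  initial <- intersect(initial, candidate_codes(data_subset))
  if (!length(initial)) stop("no candidate features to score", call. = FALSE)
  y <- class_values(data_subset)
  if (length(unique(y)) < 2L)
    warning("data subset ", subset_id, " contains a single class; ",
            "all gains are 0 and every feature is kept", call. = FALSE)
  gains <- vapply(initial, function(f) compute_gain(data_subset, f),
                  numeric(1L))
  r <- compute_threshold(gains)
  kept <- initial[gains >= r]
  report <- structure(list(
    subset_id = as.integer(subset_id),
    dataset_entropy = entropy_of(y),
    gains = gains,
    threshold = r,
    n_candidates = length(initial)
  ), class = "gain_report")
  list(features = kept, report = report)
}

#' @export
print.gain_report <- function(x, ...) {
  cat(sprintf("<gain_report> subset %d: Entropy(S) = %.4f bits, r = %.5f, %d candidates\n",
              x$subset_id, x$dataset_entropy, x$threshold, x$n_candidates))
  g <- sort(x$gains, decreasing = TRUE)
  print(round(g, 5))
  invisible(x)
}

#' Entropy-notion feature selection over three data subsets
#'
#' The full filter: the cohort is partitioned into three disjoint, exhaustive,
#' stratified subsets `D1..D3` (equal sizes within one row per class, class
#' proportions preserved, assignment driven by `seed`). Within each subset
#' every candidate feature's information gain is computed independently, the
#' range threshold `r = (max - min) / n` is applied, and the three surviving
#' sets `F1..F3` are united: `F = F1 U F2 U F3`. Scoring each subset is a
#' single pass over its candidate features, so the run time grows linearly in
#' the number of features.
#'
#' @param data A discrete, imputed [cohort()] with at least 3 rows.
#' @param n_subsets Number of partitions (fixed at 3).
#' @param seed Integer seed for the stratified partition.
#' @return A `"selection_result"`: `initial_features` (`F0`),
#'   `per_subset_features` (list `F1..F3`), `selected_features` (the union
#'   `F`, in `F0` order), `gain_reports` (three [select_subset()] reports) and
#'   `subset_assignment` (the partition index of every row).
#' @export
select_features <- function(data, n_subsets = 3L, seed = 42L) {
  assert_cohort(data)
  n_subsets <- as.integer(n_subsets)
  n <- nrow(data$data)
  if (n < n_subsets)
    stop("need at least ", n_subsets, " rows to form ", n_subsets,
         " subsets", call. = FALSE)
  f0 <- candidate_codes(data)
  if (!length(f0)) stop("no candidate features", call. = FALSE)

  assignment <- stratified_partition(class_values(data), n_subsets,
                                     derive_seed(seed, "partition"))
  per_subset <- vector("list", n_subsets)
  reports <- vector("list", n_subsets)
  for (k in seq_len(n_subsets)) {
    dk <- cohort_rows(data, assignment == k)
    res <- select_subset(dk, f0, subset_id = k)
    per_subset[[k]] <- res$features
    reports[[k]] <- res$report
  }
  selected <- f0[f0 %in% unique(unlist(per_subset))]
  structure(list(
    initial_features = f0,
    per_subset_features = per_subset,
    selected_features = selected,
    gain_reports = reports,
    subset_assignment = assignment,
    seed = as.integer(seed)
  ), class = "selection_result")
}

# Disjoint exhaustive stratified assignment into 1..k, sizes equal within
# one row per class, seeded.
stratified_partition <- function(y, k, seed) {
  assignment <- integer(length(y))
  withr::with_seed(seed, {
    for (idx in split(seq_along(y), y)) {
      perm <- if (length(idx) > 1L) sample(idx) else idx
      assignment[perm] <- rep_len(seq_len(k), length(perm))
    }
  })
  assignment
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> |F0| = %d -> |F| = %d\n",
              length(x$initial_features), length(x$selected_features)))
  for (k in seq_along(x$per_subset_features))
    cat(sprintf("  F%d (%d): %s\n", k, length(x$per_subset_features[[k]]),
                paste(x$per_subset_features[[k]], collapse = " ")))
  cat(sprintf("  F: %s\n", paste(x$selected_features, collapse = " ")))
  invisible(x)
}

#' Serialize a selection result to JSON or YAML
#'
#' @param x A `"selection_result"`.
#' @param path Output path; format chosen by extension (`.json` or
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  payload <- list(
    initial_features = x$initial_features,
    per_subset_features = x$per_subset_features,
    selected_features = x$selected_features,
    gain_reports = lapply(x$gain_reports, function(r)
      list(subset_id = r$subset_id, dataset_entropy = r$dataset_entropy,
           gains = as.list(r$gains), threshold = r$threshold,
           n_candidates = r$n_candidates)),
    seed = x$seed
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
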