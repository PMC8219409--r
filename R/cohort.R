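#' Construct a validated cohort dataset
#'
#' A cohort couples a rectangular record table (one row per pregnancy) with a
#' schema describing every column and the code of the binary class column.
#' After validation the target column holds exactly the values 0 (term birth)
#' and 1 (preterm birth, the positive class); missing values elsewhere are
#' kept as `NA`, never dropped.
#'
#' @param data Data frame of records. Columns are matched to schema codes;
#'   internal column order follows the schema.
#' @param schema Schema data frame (see [feature_spec()]); if `NULL`, a schema
#'   is inferred from the data: numeric columns become `numeric`, 0/1 columns
#'   `binary`, character columns `categorical`, a column named `PID` the
#'   identifier, and `class_column` the target.
#' @param class_column Code of the target column (default `"PTB"`).
#' @return An object of class `"cohort"`: a list with elements `data`,
#'   `schema`, `class_column`.
#' @export
cohort <- function(data, schema = NULL, class_column = "PTB") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(schema)) schema <- infer_schema(data, class_column)
  validate_schema(schema)
  target_code <- schema$code[schema$role == "target"]
  if (!identical(class_column, target_code))
    stop("class_column ('", class_column, "') does not match the schema ",
         "target ('", target_code, "')", call. = FALSE)

  missing_cols <- setdiff(schema$code, names(data))
  if (length(missing_cols))
    stop("data is missing schema column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(data), schema$code)
  if (length(extra))
    stop("data has column(s) not in schema: ", paste(extra, collapse = ", "),
         call. = FALSE)
  data <- data[, schema$code, drop = FALSE]

  y <- data[[class_column]]
  if (anyNA(y))
    stop("target column '", class_column, "' contains missing values (rows ",
         paste(utils::head(which(is.na(y)), 5L), collapse = ", "), ")",
         call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("target column '", class_column, "' must contain only 0/1; ",
         "offending rows: ",
         paste(utils::head(which(!y %in% c(0, 1)), 5L), collapse = ", "),
         call. = FALSE)
  data[[class_column]] <- as.integer(y)

  structure(list(data = data, schema = schema, class_column = class_column),
            class = "cohort")
}

infer_schema <- function(data, class_column) {
  if (!class_column %in% names(data))
    stop("target column '", class_column, "' not found in data", call. = FALSE)
  specs <- lapply(names(data), function(code) {
    x <- data[[code]]
    if (identical(code, class_column))
      return(feature_spec(code, code, "binary", "target"))
    role <- if (identical(code, "PID")) "identifier" else "candidate"
    kind <- if (is.numeric(x)) {
      obs <- x[!is.na(x)]
      if (length(obs) && all(obs %in% c(0, 1))) "binary" else "numeric"
    } else "categorical"
    feature_spec(code, code, kind, role)
  })
  do.call(rbind, specs)
}

is_cohort <- function(x) inherits(x, "cohort")

assert_cohort <- function(x) {
  if (!is_cohort(x)) stop("expected a cohort object", call. = FALSE)
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records x %d features (target: %s)\n",
              nrow(x$data), nrow(x$schema), x$class_column))
  s <- summary(x)
  cat(sprintf("  classes: %s | minority fraction %.4f\n",
              paste(sprintf("%s=%d", names(s$class_counts), s$class_counts),
                    collapse = ", "),
              s$minority_fraction))
  invisible(x)
}

# Row subset keeping schema and class column.
cohort_rows <- function(x, i) {
  assert_cohort(x)
  out <- x
  out$data <- x$data[i, , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

# Restrict candidates to `codes`; identifier and target columns are kept.
cohort_restrict <- function(x, codes) {
  assert_cohort(x)
  keep <- x$schema$role != "candidate" | x$schema$code %in% codes
  out <- x
  out$schema <- x$schema[keep, , drop = FALSE]
  rownames(out$schema) <- NULL
  out$data <- x$data[, out$schema$code, drop = FALSE]
  out
}

candidate_codes <- function(x) x$schema$code[x$schema$role == "candidate"]

class_values <- function(x) x$data[[x$class_column]]

#' Summarize a cohort dataset
#'
#' @param object A [cohort()].
#' @param ... Unused.
#' @return A `"cohort_summary"` list: `n_features`, `n_classes`, `n_rows`,
#'   `class_counts` (named, levels 0 and 1 always present) and
#'   `minority_fraction` = smallest class count / total rows (0 for an empty
#'   class; `NA` for an empty cohort).
#' @export
summary.cohort <- function(object, ...) {
  y <- class_values(object)
  counts <- table(factor(y, levels = c(0L, 1L)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- nrow(object$data)
  structure(list(
    n_features = nrow(object$schema),
    n_classes = 2L,
    n_rows = n,
    class_counts = counts,
    minority_fraction = if (n > 0L) min(counts) / n else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  features: %d   classes: %d   rows: %d\n",
              x$n_features, x$n_classes, x$n_rows))
  cat(sprintf("  class counts: %s\n",
              paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                    collapse = ", ")))
  cat(sprintf("  minority fraction: %.4f\n", x$minority_fraction))
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects an RFC-4180-style file with a header row of feature codes. Empty
#' cells and the literal string `NA` are read as missing; missing cells are
#' marked, never dropped. The target column must contain only 0/1 with no
#' missing values.
#'
#' @param path Path to a CSV file.
#' @param schema Optional schema; when given, file columns must be a subset
#'   of the schema codes (and must include the target). When `NULL` the
#'   schema is inferred from the data.
#' @param class_column Target column code (default `"PTB"`).
#' @param strict When the file contains columns not in `schema`: `TRUE`
#'   (default) rejects the file, `FALSE` drops them with a warning.
#' @return A validated [cohort()].
#' @export
read_cohort_csv <- function(path, schema = NULL, class_column = "PTB",
                            strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                    check.names = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.null(schema)) {
    validate_schema(schema)
    unknown <- setdiff(names(df), schema$code)
    if (length(unknown)) {
      msg <- paste0("column(s) not in schema: ",
                    paste(unknown, collapse = ", "))
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; dropped", call. = FALSE)
      df <- df[, setdiff(names(df), unknown), drop = FALSE]
    }
    target_code <- schema$code[schema$role == "target"]
    if (!target_code %in% names(df))
      stop("target column '", target_code, "' absent from ", path,
           call. = FALSE)
    schema <- schema[schema$code %in% names(df), , drop = FALSE]
    rownames(schema) <- NULL
  }
  cohort(df, schema = schema, class_column = class_column)
}

#' Write a cohort to CSV
#'
#' Writes a header row of feature codes followed by one line per record.
#' Missing values are written as empty cells, so `read_cohort_csv()` on the
#' result reproduces the dataset exactly (and a second write is byte-identical
#' to the first).
#'
#' @param data A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  assert_cohort(data)
  chr <- vapply(data$data, is.character, logical(1L))
  for (col in names(data$data)[chr]) {
    v <- data$data[[col]]
    if (any(grepl('[",\n]', v[!is.na(v)])))
      stop("column '", col, "' contains quote/comma/newline characters; ",
           "not representable in the unquoted CSV dialect", call. = FALSE)
  }
  utils::write.csv(data$data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
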