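#' Impute missing values
#'
#' Numeric features are imputed with the mean of their observed values, so
#' the column mean is unchanged by imputation. Ordinal, binary and
#' categorical features — for which a mean is undefined — are imputed with the
#' mode of the observed values; ties between equally frequent values are
#' broken toward the smallest value (deterministic). Observed cells are never
#' altered. The target column must already be complete.
#'
#' @param data A [cohort()].
#' @return A cohort with no missing cells.
#' @export
impute_missing <- function(data) {
  assert_cohort(data)
  df <- data$data
  for (i in seq_len(nrow(data$schema))) {
    code <- data$schema$code[i]
    if (data$schema$role[i] == "target") next
    x <- df[[code]]
    if (!anyNA(x)) next
    obs <- x[!is.na(x)]
    if (!length(obs))
      stop("feature '", code, "' is entirely missing; cannot impute",
           call. = FALSE)
    fill <- if (data$schema$value_kind[i] == "numeric" && is.numeric(x)) {
      mean(obs)
    } else {
      tab <- table(obs)
      top <- names(tab)[tab == max(tab)]
      top <- sort(top)[1L]          # tie -> smallest value
      if (is.numeric(x)) as.numeric(top) else top
    }
    x[is.na(x)] <- fill
    df[[code]] <- x
  }
  data$data <- df
  data
}

#' Fit a discretization map
#'
#' Builds per-feature cut points turning each continuous (`value_kind =
#' "numeric"`) feature into a finite set of ordered interval codes
#' `0..k-1`. Three methods are available:
#'
#' * `mdl_entropy` (default): supervised entropy minimization in the
#'   Fayyad–Irani style. Candidate boundaries are the midpoints between
#'   adjacent distinct values whose neighbourhoods contain different class
#'   labels; the cut minimising the class entropy of the induced partition is
#'   accepted when it passes the minimum-description-length criterion, then
#'   each side is split recursively. A feature that earns no cut becomes a
#'   single bin.
#' * `equal_width`: `bins` intervals of equal width over the observed range.
#' * `equal_frequency`: boundaries at quantiles so bins hold (approximately)
#'   equal numbers of observations.
#'
#' Intervals are half-open `[a, b)`: a value equal to a boundary falls in the
#' upper bin. The outermost intervals are open, so the map covers the whole
#' real line.
#'
#' @param data A [cohort()] without missing values.
#' @param method Discretization method (see above).
#' @param bins Number of bins for the unsupervised methods (>= 2). Clamped
#'   with a warning when a feature has fewer distinct values.
#' @return A `"discretizer"` object: per-feature boundary vectors plus the
#'   method and bin-count used.
#' @export
fit_discretizer <- function(data,
                            method = c("mdl_entropy", "equal_frequency",
                                       "equal_width"),
                            bins = 5L) {
  assert_cohort(data)
  method <- match.arg(method)
  if (method != "mdl_entropy" && bins < 2L)
    stop("bins must be >= 2 for unsupervised methods", call. = FALSE)
  num_codes <- data$schema$code[data$schema$value_kind == "numeric" &
                                data$schema$role == "candidate"]
  y <- class_values(data)
  cuts <- list()
  for (code in num_codes) {
    x <- data$data[[code]]
    if (anyNA(x))
      stop("feature '", code, "' has missing values; impute first",
           call. = FALSE)
    cuts[[code]] <- switch(method,
      equal_width = cuts_equal_width(x, bins),
      equal_frequency = cuts_equal_frequency(x, bins),
      mdl_entropy = cuts_mdl(x, y))
  }
  structure(list(cuts = cuts, method = method, bins = as.integer(bins)),
            class = "discretizer")
}

cuts_equal_width <- function(x, bins) {
  k <- min(bins, length(unique(x)))
  if (k < bins)
    warning("bins clamped to ", k, " (fewer distinct values)", call. = FALSE)
  if (k <= 1L) return(numeric(0L))        # constant feature -> single bin
  rng <- range(x)
  rng[1L] + diff(rng) * seq_len(k - 1L) / k
}

cuts_equal_frequency <- function(x, bins) {
  k <- min(bins, length(unique(x)))
  if (k < bins)
    warning("bins clamped to ", k, " (fewer distinct values)", call. = FALSE)
  if (k <= 1L) return(numeric(0L))
  b <- unique(stats::quantile(x, probs = seq_len(k - 1L) / k, type = 1L,
                              names = FALSE))
  # quantile of type 1 returns observed values; cut strictly between
  # neighbours so equal values stay together
  sx <- sort(unique(x))
  vapply(b, function(v) {
    above <- sx[sx > v]
    if (length(above)) (v + above[1L]) / 2 else v + 0.5
  }, numeric(1L))
}

# Fayyad-Irani style MDL cut search: recursive binary splits on class-boundary
# midpoints, accepted when information gain exceeds the MDL threshold.
cuts_mdl <- function(x, y) {
  rec <- function(xs, ys) {
    n <- length(xs)
    sx <- sort(unique(xs))
    if (n < 2L || length(sx) < 2L) return(numeric(0L))
    cand <- candidate_midpoints(xs, ys, sx)
    if (!length(cand)) return(numeric(0L))
    h_parent <- entropy_of(ys)
    best <- NULL
    best_gain <- -Inf
    for (cut in cand) {
      left <- ys[xs < cut]; right <- ys[xs >= cut]
      g <- h_parent - (length(left) / n) * entropy_of(left) -
        (length(right) / n) * entropy_of(right)
      if (g > best_gain + 1e-12) { best_gain <- g; best <- cut }
    }
    left <- ys[xs < best]; right <- ys[xs >= best]
    k  <- length(unique(ys))
    k1 <- length(unique(left)); k2 <- length(unique(right))
    delta <- log2(3^k - 2) -
      (k * entropy_of(ys) - k1 * entropy_of(left) - k2 * entropy_of(right))
    if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0L))
    c(rec(xs[xs < best], left), best, rec(xs[xs >= best], right))
  }
  sort(rec(x, y))
}

candidate_midpoints <- function(xs, ys, sx) {
  # midpoints between adjacent distinct values whose label sets differ
  labs <- lapply(sx, function(v) unique(ys[xs == v]))
  keep <- vapply(seq_len(length(sx) - 1L), function(i) {
    length(labs[[i]]) > 1L || length(labs[[i + 1L]]) > 1L ||
      labs[[i]] != labs[[i + 1L]]
  }, logical(1L))
  (sx[-length(sx)] + sx[-1L])[keep] / 2
}

entropy_of <- function(y) {
  if (!length(y)) return(0)
  p <- tabulate(factor(y)) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Apply a discretization map
#'
#' Replaces every `numeric` candidate feature with its ordinal bin code and
#' marks it `ordinal` in the schema, so re-applying the map to the result is
#' the identity. Non-numeric features pass through untouched.
#'
#' @param data A [cohort()] with no missing numeric cells.
#' @param map A `"discretizer"` from [fit_discretizer()].
#' @return The discretized cohort.
#' @export
apply_discretizer <- function(data, map) {
  assert_cohort(data)
  stopifnot(inherits(map, "discretizer"))
  for (i in seq_len(nrow(data$schema))) {
    if (data$schema$value_kind[i] != "numeric" ||
        data$schema$role[i] != "candidate") next
    code <- data$schema$code[i]
    b <- map$cuts[[code]]
    if (is.null(b))
      stop("numeric feature '", code, "' has no entry in the discretizer",
           call. = FALSE)
    x <- data$data[[code]]
    if (anyNA(x))
      stop("feature '", code, "' has missing values; impute first",
           call. = FALSE)
    data$data[[code]] <- as.integer(findInterval(x, b))   # [a, b): ties up
    data$schema$value_kind[i] <- "ordinal"
  }
  data
}

#' Serialize a discretizer to or from YAML
#'
#' @param map A `"discretizer"`.
#' @param path File path.
#' @return `read_discretizer_yaml` returns a `"discretizer"`;
#'   `write_discretizer_yaml` returns `path` invisibly.
#' @export
write_discretizer_yaml <- function(map, path) {
  stopifnot(inherits(map, "discretizer"))
  yaml::write_yaml(list(method = map$method, bins = map$bins,
                        cuts = lapply(map$cuts, as.numeric)), path,
                   precision = 12L)
  invisible(path)
}

#' @rdname write_discretizer_yaml
#' @export
read_discretizer_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(list(cuts = lapply(raw$cuts, function(v) as.numeric(unlist(v))),
                 method = raw$method, bins = as.integer(raw$bins)),
            class = "discretizer")
}
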