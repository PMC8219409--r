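#' Balancing configuration
#'
#' @param target_minority_fraction Desired minority share after balancing, in
#'   (0, 0.5] (default 0.5, i.e. approximately half the dataset).
#' @param k_neighbors Number of nearest minority neighbours considered when
#'   interpolating (default 5); clamped with a warning when the minority
#'   class is smaller than `k_neighbors + 1`.
#' @param seed Integer seed driving neighbour and interpolation draws.
#' @return A `"balance_config"` list.
#' @export
balance_config <- function(target_minority_fraction = 0.5, k_neighbors = 5L,
                           seed = 42L) {
  stopifnot(target_minority_fraction > 0, target_minority_fraction <= 0.5,
            k_neighbors >= 1L)
  structure(list(target_minority_fraction = target_minority_fraction,
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "balance_config")
}

#' Oversample the minority class
#'
#' Appends synthetic minority (PTB, label 1) rows until the minority share
#' reaches the configured target. The default method is SMOTE: each synthetic
#' row is a linear interpolation between a randomly chosen minority row and
#' one of its `k_neighbors` nearest minority neighbours (Euclidean distance
#' on the feature codes), with a uniform interpolation factor in \[0, 1\];
#' integer-coded (ordinal) features are rounded half-up back to valid codes,
#' so every synthetic row stays inside the minority class's observed min-max
#' envelope. `method = "duplicate"` instead replicates existing minority rows
#' verbatim. Original rows are retained unchanged in either mode, and no
#' majority rows are added or removed.
#'
#' @param data A [cohort()] with numeric/ordinal-coded candidate features
#'   (post-discretization codes are fine) and a binary target.
#' @param config A [balance_config()].
#' @param method `"smote"` (default) or `"duplicate"`.
#' @return The balanced cohort: original rows first, synthetic rows appended.
#'   Returned unchanged when the minority share is already at or above the
#'   target.
#' @export
smote_balance <- function(data, config = balance_config(),
                          method = c("smote", "duplicate")) {
  assert_cohort(data)
  method <- match.arg(method)
  stopifnot(inherits(config, "balance_config"))
  y <- class_values(data)
  n <- length(y)
  n_min <- sum(y == 1L)
  n_maj <- n - n_min
  if (n_min < 2L)
    stop("minority class has fewer than 2 rows; cannot oversample",
         call. = FALSE)
  target <- config$target_minority_fraction
  if (n_min / n >= target) return(data)
  # minority count m solving m / (m + n_maj) = target
  n_new <- round_half_up(target * n_maj / (1 - target)) - n_min
  if (n_new <= 0L) return(data)

  feats <- candidate_codes(data)
  not_num <- feats[!vapply(data$data[feats], is.numeric, logical(1L))]
  if (length(not_num))
    stop("candidate feature(s) not numeric/ordinal-coded: ",
         paste(not_num, collapse = ", "),
         "; discretize or encode before balancing", call. = FALSE)
  min_rows <- which(y == 1L)
  X <- as.matrix(data$data[min_rows, feats, drop = FALSE])
  integral <- apply(X, 2L, function(col) all(col == round(col)))

  k <- config$k_neighbors
  if (n_min < k + 1L) {
    k <- n_min - 1L
    warning("k_neighbors clamped to ", k, " (minority class has ", n_min,
            " rows)", call. = FALSE)
  }

  syn <- withr::with_seed(derive_seed(config$seed, "balance"), {
    if (method == "duplicate") {
      X[sample.int(n_min, n_new, replace = TRUE), , drop = FALSE]
    } else {
      d <- as.matrix(stats::dist(X))
      diag(d) <- Inf
      nn <- apply(d, 1L, function(row) order(row)[seq_len(k)])
      nn <- matrix(nn, nrow = k)               # k x n_min
      base <- sample.int(n_min, n_new, replace = TRUE)
      pick <- nn[cbind(sample.int(k, n_new, replace = TRUE), base)]
      u <- stats::runif(n_new)
      out <- X[base, , drop = FALSE] + u * (X[pick, , drop = FALSE] -
                                            X[base, , drop = FALSE])
      out[, integral] <- round_half_up(out[, integral, drop = FALSE])
      out
    }
  })

  new_rows <- as.data.frame(syn)
  names(new_rows) <- feats
  for (f in feats)                 # keep integer-typed columns integer
    if (is.integer(data$data[[f]]) && all(new_rows[[f]] == round(new_rows[[f]])))
      new_rows[[f]] <- as.integer(new_rows[[f]])
  template <- data$data[rep(min_rows[1L], n_new), , drop = FALSE]
  template[feats] <- new_rows
  id_code <- data$schema$code[data$schema$role == "identifier"]
  for (code in id_code) {
    old <- data$data[[code]]
    template[[code]] <- if (is.numeric(old)) {
      max(old, na.rm = TRUE) + seq_len(n_new)
    } else {
      sprintf("SYN-%06d", seq_len(n_new))
    }
  }
  template[[data$class_column]] <- 1L
  out <- data
  out$data <- rbind(data$data, template)
  rownames(out$data) <- NULL
  out
}
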