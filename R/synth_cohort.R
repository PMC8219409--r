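#' Synthetic cohort generator configuration
#'
#' Describes a seeded synthetic obstetric cohort with known ground truth:
#' a fixed number of records at a fixed preterm prevalence, a set of
#' informative features whose discrete value distributions differ between the
#' preterm (class 1) and term (class 0) groups, and noise features whose
#' distributions are identical in both groups. Defaults emulate the shape of
#' the study cohort the pipeline is designed for: 1300 records, 36 schema
#' features, minority prevalence 0.238 (309 of 1300 preterm), six planted
#' informative features (GA, BP, HB, PE, HT, PCS) whose population
#' information gains range from roughly 0.1 to 0.45 bits, and the remaining
#' candidates pure noise. All features are emitted as integer codes; `raw`
#' mode adds sub-bin Gaussian jitter to numeric features so the discretizer
#' has real work to do. No clinical realism is claimed for the planted
#' distributions; they are labelled fixtures.
#'
#' @param n_rows Number of records (default 1300).
#' @param prevalence Minority (preterm) fraction in \[0, 0.5\] (default 0.238).
#' @param informative Named list of planted features; each element is a list
#'   with `p_case` and `p_control`, probability vectors over value codes
#'   `0..k-1` for the preterm and term groups.
#' @param noise Named list of noise features; each element a list with `p`, a
#'   probability vector shared by both groups.
#' @param missing_rate Per-feature probability of a missing cell (default 0).
#' @param raw Emit jittered continuous values for numeric features (default
#'   `FALSE`).
#' @param seed Integer seed.
#' @param schema Cohort schema (default [default_schema()]); informative and
#'   noise names must be candidate codes of this schema.
#' @return A `"generator_config"` list.
#' @export
generator_config <- function(n_rows = 1300L, prevalence = 0.238,
                             informative = default_informative(),
                             noise = NULL, missing_rate = 0,
                             raw = FALSE, seed = 42L,
                             schema = default_schema()) {
  stopifnot(n_rows >= 1L, prevalence >= 0, prevalence <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  validate_schema(schema)
  if (is.null(noise))
    noise <- default_noise(setdiff(
      schema$code[schema$role == "candidate"], names(informative)))
  if (!length(informative) || !length(noise))
    stop("informative and noise feature lists must be non-empty",
         call. = FALSE)
  cand <- schema$code[schema$role == "candidate"]
  bad <- setdiff(c(names(informative), names(noise)), cand)
  if (length(bad))
    stop("not candidate codes of the schema: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (nm in names(informative)) {
    e <- informative[[nm]]
    if (abs(sum(e$p_case) - 1) > 1e-8 || abs(sum(e$p_control) - 1) > 1e-8 ||
        length(e$p_case) != length(e$p_control))
      stop("distributions for '", nm, "' must be equal-length and sum to 1",
           call. = FALSE)
  }
  for (nm in names(noise))
    if (abs(sum(noise[[nm]]$p) - 1) > 1e-8)
      stop("noise distribution for '", nm, "' must sum to 1", call. = FALSE)
  structure(list(n_rows = as.integer(n_rows), prevalence = prevalence,
                 informative = informative, noise = noise,
                 missing_rate = missing_rate, raw = isTRUE(raw),
                 seed = as.integer(seed), schema = schema),
            class = "generator_config")
}

# Planted class-conditional distributions. Value codes are ordered bins
# (e.g. GA code 0 = earliest gestational band). Population gains at
# prevalence 0.238: GA ~0.44, BP ~0.13, HB ~0.12, PE ~0.15, HT ~0.15,
# PCS ~0.13 bits.
default_informative <- function() {
  list(
    GA  = list(p_case = c(0.55, 0.35, 0.08, 0.02),
               p_control = c(0.02, 0.08, 0.30, 0.60)),
    BP  = list(p_case = c(0.55, 0.30, 0.15),
               p_control = c(0.15, 0.30, 0.55)),
    HB  = list(p_case = c(0.45, 0.35, 0.20),
               p_control = c(0.10, 0.30, 0.60)),
    PE  = list(p_case = c(0.50, 0.50), p_control = c(0.93, 0.07)),
    HT  = list(p_case = c(0.52, 0.48), p_control = c(0.94, 0.06)),
    PCS = list(p_case = c(0.55, 0.45), p_control = c(0.94, 0.06))
  )
}

# Class-independent noise distributions: binary indicators at assorted
# rates, a few small ordinal scales, and three 12-level month codes
# (LMP/EDD/ADD) standing in for date-derived fields.
default_noise <- function(codes) {
  month <- rep(1 / 12, 12L)
  presets <- list(
    WA  = c(0.10, 0.25, 0.30, 0.25, 0.10),
    LMP = month, EDD = month, ADD = month,
    G   = c(0.35, 0.35, 0.20, 0.10),
    P   = c(0.45, 0.35, 0.15, 0.05),
    A   = c(0.80, 0.15, 0.05),
    L   = c(0.40, 0.35, 0.20, 0.05),
    EL  = c(0.30, 0.40, 0.20, 0.10),
    H   = c(0.15, 0.35, 0.35, 0.15),
    W   = c(0.20, 0.30, 0.30, 0.20),
    BMI = c(0.25, 0.50, 0.25),
    ANC = c(0.20, 0.30, 0.30, 0.20),
    FHR = c(0.15, 0.70, 0.15),
    BW  = c(0.20, 0.60, 0.20),
    LV  = c(0.40, 0.35, 0.20, 0.05)
  )
  rates <- c(OH = 0.20, GDM = 0.08, MG = 0.03, ND = 0.60, MH = 0.15,
             LBW = 0.18, ASPX = 0.05, SB = 0.04, OB = 0.12, AN = 0.30,
             TH = 0.07, NS = 0.10)
  out <- lapply(codes, function(code) {
    if (code %in% names(presets)) return(list(p = presets[[code]]))
    if (code %in% names(rates))
      return(list(p = c(1 - rates[[code]], rates[[code]])))
    list(p = c(0.5, 0.5))
  })
  stats::setNames(out, codes)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `round(prevalence * n_rows)` minority (preterm) records and the
#' remainder majority records; each feature is sampled independently from its
#' class-conditional (informative) or shared (noise) distribution. Missing
#' cells are then injected uniformly at `missing_rate` into candidate
#' features. The same seed always yields the identical cohort.
#'
#' @param config A [generator_config()].
#' @return A list with `cohort` (a [cohort()]) and `informative`, the
#'   character vector of planted feature codes (the ground truth for
#'   recovery tests).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_rows
  n_min <- as.integer(round_half_up(config$prevalence * n))
  y <- c(rep(1L, n_min), rep(0L, n - n_min))
  schema <- config$schema
  df <- data.frame(row.names = seq_len(n))

  withr::with_seed(derive_seed(config$seed, "generate"), {
    for (i in seq_len(nrow(schema))) {
      code <- schema$code[i]
      role <- schema$role[i]
      if (role == "target") { df[[code]] <- y; next }
      if (role == "identifier") { df[[code]] <- seq_len(n); next }
      x <- if (code %in% names(config$informative)) {
        e <- config$informative[[code]]
        k <- length(e$p_case)
        out <- integer(n)
        out[y == 1L] <- sample.int(k, n_min, replace = TRUE,
                                   prob = e$p_case) - 1L
        out[y == 0L] <- sample.int(k, n - n_min, replace = TRUE,
                                   prob = e$p_control) - 1L
        out
      } else {
        p <- config$noise[[code]]$p
        sample.int(length(p), n, replace = TRUE, prob = p) - 1L
      }
      if (config$raw && schema$value_kind[i] == "numeric")
        x <- x + stats::rnorm(n, sd = 0.15)
      df[[code]] <- x
    }
    if (config$missing_rate > 0) {
      for (code in schema$code[schema$role == "candidate"]) {
        hit <- stats::runif(n) < config$missing_rate
        df[[code]][hit] <- NA
      }
    }
  })
  rownames(df) <- NULL
  list(cohort = cohort(df, schema = schema,
                       class_column = schema$code[schema$role == "target"]),
       informative = names(config$informative))
}

#' Population information gain of a planted feature
#'
#' Closed-form gain of a feature with class-conditional discrete
#' distributions: the mutual information between feature and class,
#' `H(mixture) - prevalence * H(p_case) - (1 - prevalence) * H(p_control)`
#' where the mixture is the prevalence-weighted average of the two
#' distributions. Sample gains computed by [compute_gain()] converge to this
#' value as the cohort grows. Identical per-class distributions give 0; a
#' feature deterministic given the class with balanced classes gives 1 bit.
#'
#' @param p_case,p_control Probability vectors over the same value codes.
#' @param prevalence Probability of the case (minority) class.
#' @return Gain in bits.
#' @export
expected_gain <- function(p_case, p_control, prevalence) {
  stopifnot(length(p_case) == length(p_control),
            abs(sum(p_case) - 1) < 1e-8, abs(sum(p_control) - 1) < 1e-8,
            prevalence >= 0, prevalence <= 1)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  mix <- prevalence * p_case + (1 - prevalence) * p_control
  h(mix) - prevalence * h(p_case) - (1 - prevalence) * h(p_control)
}
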