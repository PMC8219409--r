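#' Construct a single feature specification
#'
#' A feature specification describes one column of a cohort table: a short
#' code used as the CSV header, a human-readable name, the kind of values the
#' column holds, and its role in the analysis. Identifier features (such as a
#' patient id) are carried through the pipeline but are never candidates for
#' feature selection or model fitting; exactly one feature per schema has the
#' `target` role.
#'
#' @param code Short unique string identifier, e.g. `"WA"` or `"GA"`.
#' @param name Human-readable label.
#' @param value_kind One of `"numeric"`, `"ordinal"`, `"binary"`,
#'   `"categorical"`.
#' @param role One of `"candidate"`, `"identifier"`, `"target"`.
#' @return A one-row data frame with columns `code`, `name`, `value_kind`,
#'   `role`.
#' @export
#' @examples
#' feature_spec("WA", "Woman age", "numeric")
feature_spec <- function(code, name = code,
                         value_kind = c("numeric", "ordinal", "binary",
                                        "categorical"),
                         role = c("candidate", "identifier", "target")) {
  value_kind <- match.arg(value_kind)
  role <- match.arg(role)
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  data.frame(code = code, name = name, value_kind = value_kind, role = role,
             stringsAsFactors = FALSE)
}

#' Assemble and validate a cohort schema
#'
#' @param ... One-row data frames from [feature_spec()], or a single data
#'   frame with columns `code`, `name`, `value_kind`, `role`.
#' @return A validated schema data frame.
#' @export
cohort_schema <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.data.frame(parts[[1L]]) &&
      nrow(parts[[1L]]) > 1L) {
    sch <- parts[[1L]]
  } else {
    sch <- do.call(rbind, parts)
  }
  validate_schema(sch)
  sch
}

validate_schema <- function(schema) {
  req <- c("code", "name", "value_kind", "role")
  if (!is.data.frame(schema) || !all(req %in% names(schema)))
    stop("schema must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (anyDuplicated(schema$code))
    stop("duplicate feature codes in schema: ",
         paste(unique(schema$code[duplicated(schema$code)]), collapse = ", "),
         call. = FALSE)
  bad_kind <- setdiff(schema$value_kind,
                      c("numeric", "ordinal", "binary", "categorical"))
  if (length(bad_kind))
    stop("unknown value_kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  bad_role <- setdiff(schema$role, c("candidate", "identifier", "target"))
  if (length(bad_role))
    stop("unknown role: ", paste(bad_role, collapse = ", "), call. = FALSE)
  if (sum(schema$role == "target") != 1L)
    stop("schema must contain exactly one target feature", call. = FALSE)
  invisible(schema)
}

#' The default 36-feature obstetric cohort schema
#'
#' The bundled schema lists the 36 maternal features recorded for each
#' pregnancy: background details (age, education), obstetric history
#' (gravida, parity, abortions, previous caesarean section), current-pregnancy
#' measurements (blood pressure, hemoglobin, gestational age, fetal heart
#' rate), medical disorders (gestational diabetes, preeclampsia, hypertension,
#' anemia, thyroid), and the birth outcome. `PID` is the patient identifier
#' and `PTB` (preterm birth, 1 = preterm, 0 = term) is the binary target.
#'
#' @return A schema data frame with 36 rows.
#' @export
default_schema <- function() {
  f <- function(code, name, kind, role = "candidate")
    feature_spec(code, name, kind, role)
  rbind(
    f("PID",  "Patient identification",        "numeric", "identifier"),
    f("WA",   "Woman age",                     "numeric"),
    f("LMP",  "Last menstrual period",         "categorical"),
    f("EDD",  "Estimated delivery date",       "categorical"),
    f("G",    "Gravida",                       "numeric"),
    f("P",    "Parity",                        "numeric"),
    f("A",    "Abortion",                      "numeric"),
    f("L",    "Living",                        "numeric"),
    f("EL",   "Educational level",             "ordinal"),
    f("H",    "Height",                        "numeric"),
    f("W",    "Weight",                        "numeric"),
    f("BMI",  "Body mass index",               "ordinal"),
    f("BP",   "Blood pressure",                "ordinal"),
    f("HB",   "Hemoglobin",                    "numeric"),
    f("ANC",  "Antenatal care visit",          "numeric"),
    f("ADD",  "Actual delivery date",          "categorical"),
    f("OH",   "Obstetric history",             "binary"),
    f("PCS",  "Previous caesarean section",    "binary"),
    f("GA",   "Gestational age",               "numeric"),
    f("BW",   "Birth weight",                  "numeric"),
    f("GDM",  "Gestational diabetes mellitus", "binary"),
    f("FHR",  "Fetal heart rate",              "numeric"),
    f("MG",   "Multiple gestation",            "binary"),
    f("ND",   "Normal delivery",               "binary"),
    f("MH",   "Previous medical history",      "binary"),
    f("LBW",  "Low birth weight",              "binary"),
    f("ASPX", "Asphyxia",                      "binary"),
    f("HT",   "Hypertension",                  "binary"),
    f("PE",   "Preeclampsia",                  "binary"),
    f("LV",   "Live birth",                    "numeric"),
    f("SB",   "Still birth",                   "binary"),
    f("OB",   "Obesity",                       "binary"),
    f("AN",   "Anemia",                        "binary"),
    f("TH",   "Thyroid",                       "binary"),
    f("NS",   "Neonatal status",               "binary"),
    f("PTB",  "Preterm birth",                 "binary", "target")
  )
}

#' Read or write a schema as YAML
#'
#' The YAML format is a list of maps with keys `code`, `name`, `value_kind`
#' and `role`, in schema order.
#'
#' @param path File path.
#' @return `read_schema_yaml` returns a schema data frame;
#'   `write_schema_yaml` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sch <- do.call(rbind, lapply(raw, function(e)
    feature_spec(e$code, e$name %||% e$code, e$value_kind, e$role)))
  validate_schema(sch)
  sch
}

#' @rdname read_schema_yaml
#' @param schema Schema data frame.
#' @export
write_schema_yaml <- function(schema, path) {
  validate_schema(schema)
  entries <- lapply(seq_len(nrow(schema)), function(i)
    list(code = schema$code[i], name = schema$name[i],
         value_kind = schema$value_kind[i], role = schema$role[i]))
  yaml::write_yaml(entries, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
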