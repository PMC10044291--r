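# Cohort ingestion and dichotomization of raw vitals into binary signs.
#
# A cohort is an ordinary data.frame, one row per patient, with the raw
# columns below. Ternary (yes/no/missing) fields are coded 1/0/NA. The
# binary predictors used by the analysis are derived, never stored.

RAW_NUMERIC_FIELDS <- c("temperature", "heart_rate", "respiratory_rate",
                        "spo2", "sbp", "dbp", "age_years")
RAW_TERNARY_FIELDS <- c("abnormal_auscultation", "confusion", "sex_female",
                        "sputum", "history_of_fever", "dyspnea", "chest_pain",
                        "asthma", "copd", "smoker", "other_comorbidity",
                        "cxr_positive")

#' Names of the derived binary signs
#'
#' `sign_names()` lists every binary predictor that [dichotomize()] derives;
#' `analysis_signs()` lists the five candidate signs entering regression
#' models and decision rules (lung auscultation plus four vital signs;
#' blood pressure and the CRB-65 flag are excluded by default).
#'
#' @return Character vector of sign names.
#' @export
sign_names <- function() {
  c("fever_temp", "hypoxemia", "tachycardia", "tachypnea", "hypotension",
    "abnormal_auscultation", "age65", "crb65_ge1")
}

#' @rdname sign_names
#' @export
analysis_signs <- function() {
  c("abnormal_auscultation", "fever_temp", "hypoxemia",
    "tachycardia", "tachypnea")
}

#' Default dichotomization cut-offs
#'
#' Cut-off points regarded as the boundary between normal and abnormal vital
#' signs, with the boundary handling used throughout: fever is temperature
#' >= 37.8 degrees C, hypoxemia is SpO2 < 95%, tachycardia is heart rate
#' > 100/min, tachypnea is respiratory rate >= 24/min, hypotension is SBP
#' <= 90 or DBP <= 60 mmHg, old age is >= 65 years. The CRB-65 component
#' uses respiratory rate >= 30/min.
#'
#' @return Named list of numeric cut-offs.
#' @seealso [read_cutoffs()] to override from a YAML file.
#' @export
default_cutoffs <- function() {
  list(fever_temp = 37.8, hypoxemia = 95, tachycardia = 100,
       tachypnea = 24, hypotension_sbp = 90, hypotension_dbp = 60,
       age65 = 65, crb65_resp = 30)
}

#' Read cut-off overrides from a YAML file
#'
#' Unknown keys are rejected; keys not present fall back to
#' [default_cutoffs()].
#'
#' @param path Path to a flat YAML mapping of cut-off names to numbers.
#' @return Named list of cut-offs, complete over all names in
#'   [default_cutoffs()].
#' @export
read_cutoffs <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_cutoffs()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown cutoff name(s): ", paste(unknown, collapse = ", "))
  bad <- names(user)[!vapply(user, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad) > 0L)
    stop("cutoff(s) not a single finite number: ", paste(bad, collapse = ", "))
  modifyList(defaults, user)
}

#' Validate a cohort data.frame
#'
#' Checks the physiologic range invariants (SpO2 in \[0, 100\], temperature
#' in \[30, 45\] degrees C, strictly positive heart rate, respiratory rate
#' and blood pressures where present), 0/1/NA coding of ternary fields, and
#' uniqueness of `patient_id`.
#'
#' @param cohort A cohort data.frame.
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending column and patient.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  if (!"patient_id" %in% names(cohort)) stop("cohort lacks a patient_id column")
  if (nrow(cohort) == 0L) stop("cohort is empty")
  id <- as.character(cohort$patient_id)
  if (anyDuplicated(id))
    stop("duplicate patient_id: ", id[duplicated(id)][1L])
  check_range <- function(col, lo, hi, strict_lo = FALSE) {
    if (!col %in% names(cohort)) return(invisible())
    x <- cohort[[col]]
    if (!is.numeric(x)) stop("column ", col, " is not numeric")
    bad <- !is.na(x) & (if (strict_lo) x <= lo else x < lo | x > hi)
    if (any(bad))
      stop("column ", col, " out of range for patient_id ",
           id[which(bad)[1L]], " (value ", x[which(bad)[1L]], ")")
  }
  check_range("spo2", 0, 100)
  check_range("temperature", 30, 45)
  for (col in c("heart_rate", "respiratory_rate", "sbp", "dbp"))
    check_range(col, 0, Inf, strict_lo = TRUE)
  for (col in intersect(RAW_TERNARY_FIELDS, names(cohort))) {
    x <- cohort[[col]]
    if (!all(is.na(x) | x %in% c(0, 1)))
      stop("column ", col, " must be coded 0/1/NA")
  }
  invisible(cohort)
}

# Three-valued OR over 0/1/NA vectors: 1 if any component is a known 1,
# 0 if all are known 0, NA otherwise.
ternary_any <- function(...) {
  m <- cbind(...)
  any1 <- rowSums(m == 1, na.rm = TRUE) > 0
  all0 <- rowSums(is.na(m) | m == 1) == 0
  ifelse(any1, 1, ifelse(all0, 0, NA))
}

#' Derive binary signs from raw measurements
#'
#' Applies the stated inequality direction and boundary inclusion for each
#' sign (see [default_cutoffs()]): a temperature of exactly 37.8 is febrile
#' (inclusive), an SpO2 of exactly 95 is not hypoxemic (strict), a heart
#' rate of exactly 100 is not tachycardic (strict), a respiratory rate of
#' exactly 24 is tachypneic (inclusive). Missing raw values propagate to
#' missing signs; no error is ever raised for missingness. The CRB-65 flag
#' (`crb65_ge1`) is derived from the standard definition: confusion,
#' respiratory rate >= 30/min, hypotension, or age >= 65.
#'
#' @param cohort A cohort data.frame (see [validate_cohort()]).
#' @param cutoffs Named list of cut-offs, as from [default_cutoffs()].
#' @return A data.frame of 0/1/NA signs (columns [sign_names()]) plus
#'   `patient_id` and the `cxr_positive` reference outcome when present.
#' @examples
#' rec <- data.frame(patient_id = "p1", temperature = 37.8, spo2 = 95,
#'                   heart_rate = 100, respiratory_rate = 24,
#'                   sbp = 120, dbp = 70, age_years = 50,
#'                   abnormal_auscultation = 1, cxr_positive = 0)
#' dichotomize(rec)[, c("fever_temp", "hypoxemia", "tachycardia", "tachypnea")]
#' @export
dichotomize <- function(cohort, cutoffs = default_cutoffs()) {
  stopifnot(is.data.frame(cohort))
  n <- nrow(cohort)
  col <- function(nm) if (nm %in% names(cohort)) cohort[[nm]] else rep(NA_real_, n)
  as01 <- function(x) ifelse(is.na(x), NA, as.numeric(x))
  hypotension <- ternary_any(as01(col("sbp") <= cutoffs$hypotension_sbp),
                             as01(col("dbp") <= cutoffs$hypotension_dbp))
  # one hypotensive reading suffices even when the other pressure is missing,
  # but both must be known normal to call the sign absent
  signs <- data.frame(
    patient_id = if ("patient_id" %in% names(cohort))
      as.character(cohort$patient_id) else sprintf("row%d", seq_len(n)),
    fever_temp  = as01(col("temperature") >= cutoffs$fever_temp),
    hypoxemia   = as01(col("spo2") < cutoffs$hypoxemia),
    tachycardia = as01(col("heart_rate") > cutoffs$tachycardia),
    tachypnea   = as01(col("respiratory_rate") >= cutoffs$tachypnea),
    hypotension = hypotension,
    abnormal_auscultation = as01(col("abnormal_auscultation") == 1),
    age65 = as01(col("age_years") >= cutoffs$age65),
    stringsAsFactors = FALSE
  )
  signs$crb65_ge1 <- ternary_any(
    as01(col("confusion") == 1),
    as01(col("respiratory_rate") >= cutoffs$crb65_resp),
    hypotension,
    signs$age65)
  if ("cxr_positive" %in% names(cohort))
    signs$cxr_positive <- as01(cohort$cxr_positive == 1)
  signs
}

#' Restrict a cohort to complete cases
#'
#' Keeps, in their original order, the patients for whom every required sign
#' and the reference outcome are non-missing after dichotomization. This is
#' a complete-case policy: no imputation is performed.
#'
#' @param cohort A cohort data.frame containing a `cxr_positive` column.
#' @param required Character vector of sign names that must be non-missing;
#'   defaults to the five candidate analysis signs.
#' @param cutoffs Cut-offs used for the derivation.
#' @return The subcohort, with attributes `provenance` (a one-line
#'   description) and `n_dropped`. An empty result is permitted and flagged
#'   in the provenance.
#' @export
complete_cases <- function(cohort, required = analysis_signs(),
                           cutoffs = default_cutoffs()) {
  bad <- setdiff(required, sign_names())
  if (length(bad) > 0L)
    stop("unknown sign name(s) in `required`: ", paste(bad, collapse = ", "))
  if (!"cxr_positive" %in% names(cohort))
    stop("cohort lacks the cxr_positive reference outcome")
  signs <- dichotomize(cohort, cutoffs)
  keep_mat <- cbind(as.matrix(signs[, required, drop = FALSE]),
                    signs$cxr_positive)
  keep <- rowSums(is.na(keep_mat)) == 0L
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "provenance") <- sprintf(
    "complete cases on {%s, outcome}: kept %d of %d%s",
    paste(required, collapse = ", "), sum(keep), length(keep),
    if (sum(keep) == 0L) " [EMPTY]" else "")
  out
}

#' Read a cohort from CSV
#'
#' Expects RFC 4180 CSV with a header row, one row per patient. Ternary
#' fields are coded `0`/`1`/empty. A `schema` may map CSV column names onto
#' the canonical field names; unmapped unknown columns are preserved
#' untouched as opaque extras.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical field
#'   names to the CSV column names that hold them, e.g.
#'   `c(spo2 = "oxygen_sat")`.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path, schema = NULL) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "")
  if (!is.null(schema)) {
    missing_cols <- setdiff(unname(schema), names(raw))
    if (length(missing_cols) > 0L)
      stop("schema maps to column(s) absent from ", path, ": ",
           paste(missing_cols, collapse = ", "))
    idx <- match(unname(schema), names(raw))
    names(raw)[idx] <- names(schema)
  }
  if (!"patient_id" %in% names(raw))
    stop("schema error: no patient_id column in ", path)
  for (colnm in intersect(c(RAW_NUMERIC_FIELDS, RAW_TERNARY_FIELDS), names(raw))) {
    x <- raw[[colnm]]
    conv <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(conv)
    if (any(bad))
      stop("unparseable value '", x[which(bad)[1L]], "' in column ", colnm,
           " for patient_id ", raw$patient_id[which(bad)[1L]])
    raw[[colnm]] <- conv
  }
  validate_cohort(raw)
  raw
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values are written as empty fields so
#' that a write/read round trip is the identity on all fields.
#'
#' @param cohort A cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "", quote = TRUE)
  invisible(path)
}
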