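# Canonical patient-record schema: one row per surgical episode.
# Every generator, scoring engine and pipeline stage speaks this schema.

.surgrisk_levels <- list(
  sex             = c("male", "female"),
  urgency         = c("elective", "expedited", "urgent", "immediate"),
  severity        = c("minor", "intermediate", "major", "xmajor", "complex"),
  specialty       = c("gastrointestinal", "gynae_urology", "neuro_spinal",
                      "orthopaedic", "thoracic_cardiac", "vascular", "other"),
  malignancy      = c("none", "primary", "nodal", "metastatic"),
  diabetes        = c("none", "type1", "type2_diet", "type2_oral",
                      "type2_insulin"),
  ecg             = c("normal", "af_60_90", "other_abnormal"),
  blood_loss      = c("<=100", "101-500", "501-999", ">=1000"),
  soiling         = c("none", "serous", "local_pus", "free"),
  procedure_count = c("1", "2", ">2"),
  country         = c("UK", "ANZ")
)

# preoperative labs/vitals eligible for normal-value imputation
.surgrisk_lab_fields <- c("systolic_bp", "pulse", "gcs", "haemoglobin",
                          "wbc", "urea", "sodium", "potassium", "ecg")

.surgrisk_flag_fields <- c("cad", "cardiac_failure", "dementia", "copd",
                           "cirrhosis", "renal_disease")

.surgrisk_method_fields <- c("method_clinical", "method_asa", "method_sort",
                             "method_ppossum", "method_srs",
                             "method_other_tool")

.surgrisk_columns <- c(
  "patient_id", "age_years", "sex", "asa_ps", "urgency", "severity",
  "specialty", "malignancy", .surgrisk_flag_fields, "diabetes",
  "systolic_bp", "pulse", "gcs", "haemoglobin", "wbc", "urea", "sodium",
  "potassium", "ecg", "blood_loss", "soiling", "procedure_count",
  "subjective_category", .surgrisk_method_fields, "death30_inpatient",
  "country", "obstetric", "ambulatory", "under18"
)

#' Canonical cohort column names
#'
#' Returns the fixed column set of a cohort table: one row per surgical
#' episode, demographics, ASA-PS, urgency, procedure severity, specialty,
#' malignancy status, comorbidity flags, preoperative physiology/labs,
#' operative fields, the 6-category subjective risk estimate, assessment
#' method flags, the 30-day inpatient death outcome, and eligibility flags.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() .surgrisk_columns

#' Validate a cohort table against the canonical schema
#'
#' Checks column presence, categorical level membership and basic range
#' invariants (ASA-PS in 1..5, outcome in \{0,1\}, subjective category in
#' 1..6 when present, age at least 18 unless flagged `under18`). Rows may
#' carry missing labs; structural fields must be populated.
#'
#' @param cohort A data frame.
#' @return Invisibly, `cohort`; stops with a message naming offending rows
#'   otherwise.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.surgrisk_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_rows <- function(ok, what) {
    if (any(!ok, na.rm = FALSE)) {
      idx <- which(!ok | is.na(ok))
      stop(sprintf("invalid %s in rows: %s", what,
                   paste(utils::head(idx, 5L), collapse = ", ")))
    }
  }
  for (v in names(.surgrisk_levels)) {
    x <- cohort[[v]]
    ok <- is.na(x) | x %in% .surgrisk_levels[[v]]
    if (any(!ok)) {
      stop(sprintf("unknown level(s) in column '%s': %s (rows %s)", v,
                   paste(unique(x[!ok]), collapse = ", "),
                   paste(utils::head(which(!ok), 5L), collapse = ", ")))
    }
  }
  bad_rows(cohort$asa_ps %in% 1:5, "asa_ps (must be 1..5)")
  bad_rows(cohort$death30_inpatient %in% c(0L, 1L) |
             is.na(cohort$death30_inpatient), "death30_inpatient")
  sc <- cohort$subjective_category
  bad_rows(is.na(sc) | sc %in% 1:6, "subjective_category (1..6 or missing)")
  ok_age <- is.na(cohort$age_years) | cohort$age_years >= 18 |
    cohort$under18
  bad_rows(ok_age, "age_years (>= 18 unless under18 flag)")
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' The external cohort format is a flat CSV with the fixed canonical header
#' ([cohort_columns()]), one row per episode, and missing values as empty
#' fields. No dates are stored.
#'
#' @param path File path.
#' @param cohort A cohort data frame.
#' @return `read_cohort()` returns a validated cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  logicals <- c(.surgrisk_method_fields, "obstetric", "ambulatory", "under18")
  for (v in intersect(logicals, names(cohort))) {
    cohort[[v]] <- as.logical(cohort[[v]])
  }
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
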