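# shared fixtures, built in code

# one fully populated analysis-ready record, overridable field by field
make_record <- function(...) {
  rec <- data.frame(
    patient_id = "P0000001", age_years = 45, sex = "female", asa_ps = 1L,
    urgency = "elective", severity = "intermediate",
    specialty = "orthopaedic", malignancy = "none",
    cad = FALSE, cardiac_failure = FALSE, dementia = FALSE, copd = FALSE,
    cirrhosis = FALSE, renal_disease = FALSE, diabetes = "none",
    systolic_bp = 120, pulse = 75, gcs = 15, haemoglobin = 14.0, wbc = 8.0,
    urea = 5.0, sodium = 140, potassium = 4.0, ecg = "normal",
    blood_loss = "<=100", soiling = "none", procedure_count = "1",
    subjective_category = 1L, method_clinical = TRUE, method_asa = FALSE,
    method_sort = FALSE, method_ppossum = FALSE, method_srs = FALSE,
    method_other_tool = FALSE, death30_inpatient = 0L, country = "UK",
    obstetric = FALSE, ambulatory = FALSE, under18 = FALSE,
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_cohort <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    r <- make_record(...)
    r$patient_id <- sprintf("P%07d", i)
    r
  }))
}

# independent Mann-Whitney oracle: mean pairwise concordance with ties 1/2
brute_force_auc <- function(pred, obs) {
  x <- pred[obs == 1]; y <- pred[obs == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

expit <- function(x) 1 / (1 + exp(-x))

# cohort whose outcomes truly follow the combined subjective+SORT model
simulate_combined_cohort <- function(n, seed,
                                     coefs = published_combined_coefs()) {
  coh <- generate_cohort(cohort_config(n_patients = n, seed = seed))
  coh$sort_risk_pct <- score_model(impute_normal_values(coh)$cohort,
                                   sort_spec(), percent = TRUE)
  p <- predict_combined(coh$subjective_category, coh$sort_risk_pct, coefs)
  coh$death30_inpatient <- simulate_outcomes(p, seed = seed + 1000L)
  coh
}
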