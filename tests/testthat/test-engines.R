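test_that("normal-value imputation fills only missing labs and flags them", {
  rec <- make_record(sodium = NA)
  out <- impute_normal_values(rec)
  expect_equal(out$cohort$sodium, 140)
  expect_true(out$flags$sodium)
  expect_false(any(unlist(out$flags[, names(out$flags) != "sodium"])))

  rec2 <- make_record()
  out2 <- impute_normal_values(rec2)
  expect_identical(out2$cohort, rec2)
  expect_false(any(unlist(out2$flags)))
})

test_that("every normal default scores the minimum POSSUM band", {
  rec <- make_record()
  for (v in c("systolic_bp", "pulse", "gcs", "haemoglobin", "wbc", "urea",
              "sodium", "potassium", "ecg")) {
    rec[[v]] <- NA
  }
  imp <- impute_normal_values(rec)$cohort
  ps <- possum_scores(imp)
  # age 45 scores 1; all other physiology items at their minimum band
  expect_equal(ps$physiology, 12)
  expect_equal(ps$operative, 6 + 1)  # intermediate severity scores 2
})

test_that("POSSUM sub-scores match a hand-scored high-risk record", {
  rec <- make_record(
    age_years = 72,          # 4
    cardiac_failure = TRUE,  # 4 (oedema band)
    copd = TRUE,             # 2 (mild band)
    systolic_bp = 85,        # 8
    pulse = 125,             # 8
    gcs = 10,                # 4
    haemoglobin = 9.0,       # 8
    wbc = 3.5,               # 2
    urea = 12,               # 4
    sodium = 128,            # 4
    potassium = 3.0,         # 4
    ecg = "other_abnormal",  # 8
    severity = "complex",    # 8
    procedure_count = ">2",  # 8
    blood_loss = ">=1000",   # 8
    soiling = "free",        # 8
    malignancy = "metastatic", # 8
    urgency = "immediate")   # 8
  ps <- possum_scores(rec)
  expect_equal(ps$physiology, 60)
  expect_equal(ps$operative, 48)
  risk <- score_model(rec, ppossum_spec())
  expect_equal(risk, expit(-9.065 + 0.1692 * 60 + 0.1550 * 48),
               tolerance = 1e-12)
})

test_that("imputation never raises the physiological sub-score above the
           fully observed normal-value record", {
  full <- make_record()
  blank <- full
  for (v in c("haemoglobin", "wbc", "urea", "sodium", "potassium")) {
    blank[[v]] <- NA
  }
  s_full <- possum_scores(full)$physiology
  s_blank <- possum_scores(impute_normal_values(blank)$cohort)$physiology
  expect_lte(s_blank, s_full)
})

test_that("reference-level records score expit(intercept) under any spec", {
  rec <- make_record()  # reference levels of every SORT variable
  expect_equal(score_model(rec, sort_spec()), expit(-7.366),
               tolerance = 1e-12)
  spec <- risk_model_spec("toy", intercept = -7,
                          terms = data.frame(variable = "urgency",
                                             level = "urgent",
                                             coefficient = 1.0),
                          variable_map = list(urgency = "urgency"))
  expect_equal(score_model(rec, spec), expit(-7), tolerance = 1e-12)
})

test_that("SRS is the points sum of CEPOD, BUPA severity and ASA-PS", {
  rec <- make_record(urgency = "urgent", severity = "xmajor", asa_ps = 3L)
  # CEPOD 3 + BUPA 4 + ASA 3 = 10
  expect_equal(score_model(rec, srs_spec()), expit(-9.81 + 0.84 * 10),
               tolerance = 1e-12)
  # NCEPOD expedited maps to the historical scheduled class (2)
  rec2 <- make_record(urgency = "expedited")
  expect_equal(score_model(rec2, srs_spec()),
               expit(-9.81 + 0.84 * (2 + 2 + 1)), tolerance = 1e-12)
})

test_that("scoring agrees with an independent hand-rolled linear predictor
           on random records", {
  set.seed(42)
  coh <- generate_cohort(cohort_config(n_patients = 100, seed = 42))
  coh <- impute_normal_values(coh)$cohort
  p_engine <- score_model(coh, sort_spec())
  # independent evaluation of the SORT equation, written out longhand
  lp <- -7.366 +
    1.411 * (coh$asa_ps == 3) + 2.388 * (coh$asa_ps == 4) +
    4.081 * (coh$asa_ps == 5) +
    0.712 * (coh$urgency == "expedited") +
    1.657 * (coh$urgency == "urgent") +
    2.452 * (coh$urgency == "immediate") +
    0.381 * (coh$specialty %in% c("gastrointestinal", "thoracic_cardiac",
                                  "vascular")) +
    0.667 * (coh$severity %in% c("xmajor", "complex")) +
    0.897 * (coh$malignancy != "none") +
    0.777 * (coh$age_years >= 65 & coh$age_years <= 79) +
    1.591 * (coh$age_years >= 80)
  expect_equal(p_engine, expit(lp), tolerance = 1e-12)
})

test_that("predicted risk is monotone in ASA-PS, urgency and age band", {
  spec <- sort_spec()
  base <- make_record()
  risks_asa <- vapply(1:5, function(a)
    score_model(make_record(asa_ps = a), spec), 0)
  expect_true(all(diff(risks_asa) >= 0))
  risks_urg <- vapply(c("elective", "expedited", "urgent", "immediate"),
                      function(u) score_model(make_record(urgency = u),
                                              spec), 0)
  expect_true(all(diff(risks_urg) > 0))
  risks_age <- vapply(c(50, 70, 85), function(a)
    score_model(make_record(age_years = a), spec), 0)
  expect_true(all(diff(risks_age) > 0))
})

test_that("model specs load, validate, and round-trip through JSON", {
  spec <- sort_spec()
  expect_s3_class(spec, "risk_model_spec")
  # 6 variable groups: ASA-PS, urgency, specialty flag, severity,
  # malignancy, age band
  expect_length(unique(spec$terms$variable), 6)

  path <- tempfile(fileext = ".json")
  write_model_spec(spec, path)
  spec2 <- load_model_spec(path)
  expect_equal(spec2$terms, spec$terms)
  expect_equal(spec2$intercept, spec$intercept)
  expect_equal(spec2$variable_map, spec$variable_map)

  dup <- spec
  dup$terms <- rbind(dup$terms, dup$terms[1, ])
  expect_error(validate_model_spec(dup), "duplicate")
  bad <- spec
  bad$variable_map$asa_ps <- "no_such_feature"
  expect_error(validate_model_spec(bad), "unknown feature")
})

test_that("SORT predictions on a default synthetic cohort have the expected
           median and IQR location", {
  coh <- generate_cohort(cohort_config(n_patients = 100000, seed = 11))
  sortp <- score_model(impute_normal_values(coh)$cohort, sort_spec(),
                       percent = TRUE)
  med <- stats::median(sortp)
  expect_gte(med, 0.2)
  expect_lte(med, 1.6)
})
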