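test_that("a fixed seed yields a bit-identical cohort", {
  c1 <- generate_cohort(cohort_config(n_patients = 5, seed = 7))
  c2 <- generate_cohort(cohort_config(n_patients = 5, seed = 7))
  attributes(c1) <- attributes(c1)[c("names", "row.names", "class")]
  attributes(c2) <- attributes(c2)[c("names", "row.names", "class")]
  expect_identical(c1, c2)
})

test_that("cohort mortality hits the target within binomial error", {
  coh <- generate_cohort(cohort_config(n_patients = 100000,
                                       mortality_target = 0.014,
                                       seed = 1))
  se <- sqrt(0.014 * 0.986 / 100000)
  expect_lt(abs(mean(coh$death30_inpatient) - 0.014), 3 * se)
  # the tuned true risks average exactly to the target
  expect_equal(mean(coh$true_risk), 0.014, tolerance = 1e-9)
})

test_that("empirical category shares match the configured marginals", {
  n <- 50000
  coh <- generate_cohort(cohort_config(n_patients = n, seed = 3))
  asa_target <- c(0.197, 0.450, 0.290, 0.059, 0.003)
  asa_target <- asa_target / sum(asa_target)
  obs <- as.vector(table(factor(coh$asa_ps, levels = 1:5))) / n
  se <- sqrt(asa_target * (1 - asa_target) / n)
  expect_true(all(abs(obs - asa_target) < 3 * se + 1e-9))
  urg_target <- c(0.533, 0.146, 0.292, 0.028)
  urg_target <- urg_target / sum(urg_target)
  obs_u <- as.vector(table(factor(coh$urgency,
                                  levels = c("elective", "expedited",
                                             "urgent", "immediate")))) / n
  se_u <- sqrt(urg_target * (1 - urg_target) / n)
  expect_true(all(abs(obs_u - urg_target) < 3 * se_u + 1e-9))
})

test_that("invalid frequency vectors are rejected naming the variable", {
  expect_error(cohort_config(covariate_mix = list(asa_ps = c(-0.1, 1.1))),
               "asa_ps")
  expect_error(cohort_config(covariate_mix = list(urgency = c(0.2, 0.2))),
               "urgency")
  expect_error(cohort_config(covariate_mix = list(nonsense = c(1))),
               "nonsense")
})

test_that("true risk under the data-generating model is the inverse-logit
           linear predictor", {
  rec <- make_record()
  null_spec <- risk_model_spec(
    "null", intercept = 0,
    terms = data.frame(variable = "urgency", level = "urgent",
                       coefficient = 0),
    variable_map = list(urgency = "urgency"))
  expect_equal(as.numeric(assign_true_risk(rec, null_spec)), 0.5)

  int_spec <- null_spec
  int_spec$intercept <- -4.249
  expect_equal(as.numeric(assign_true_risk(rec, int_spec)),
               expit(-4.249), tolerance = 1e-12)
  expect_equal(round(as.numeric(assign_true_risk(rec, int_spec)), 4),
               0.0141)
})

test_that("clinician categories bin the biased noisy logit of true risk", {
  noiseless <- list(slope = 1, bias = 0, noise = 0)
  expect_identical(simulate_subjective(0.004, noiseless), 1L)
  expect_identical(simulate_subjective(0.03, noiseless), 3L)
  expect_identical(simulate_subjective(c(0.02, 0.6), noiseless),
                   c(2L, 6L))
  # positive bias shifts categories upward
  biased <- list(slope = 1, bias = 2, noise = 0)
  expect_gte(simulate_subjective(0.03, biased), 3L)
  expect_error(simulate_subjective(0, noiseless), "strictly inside")
})

test_that("generated clinicians overpredict risk yet discriminate well", {
  coh <- generate_cohort(cohort_config(n_patients = 50000, seed = 21))
  obs_by_cat <- tapply(coh$death30_inpatient, coh$subjective_category,
                       mean) * 100
  mids <- midpoint_of(as.integer(names(obs_by_cat)))
  expect_true(all(obs_by_cat < mids))
  roc <- auroc_ordinal(coh$subjective_category, coh$death30_inpatient)
  expect_gte(roc$auroc, 0.80)
  expect_lte(roc$auroc, 0.95)
})

test_that("outcome simulation is Bernoulli with the requested rates", {
  expect_identical(simulate_outcomes(rep(0, 10)), rep(0L, 10))
  expect_identical(simulate_outcomes(rep(1, 10)), rep(1L, 10))
  y <- simulate_outcomes(rep(0.25, 40000), seed = 9)
  expect_lt(abs(mean(y) - 0.25), 3 * sqrt(0.25 * 0.75 / 40000))
  expect_error(simulate_outcomes(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("lab missingness concentrates in fitter (low ASA) patients", {
  coh <- generate_cohort(cohort_config(n_patients = 50000, seed = 13))
  miss <- is.na(coh$haemoglobin)
  rate_by_asa <- tapply(miss, coh$asa_ps, mean)
  expect_gt(rate_by_asa[["1"]], rate_by_asa[["3"]])
  expect_gt(rate_by_asa[["2"]], rate_by_asa[["4"]])
  # overall missingness near the ASA-weighted configured rate
  expect_gt(mean(miss), 0.10)
  expect_lt(mean(miss), 0.30)
})

test_that("hosmer-lemeshow on the true risks rejects at roughly the nominal
           rate over repeated seeds", {
  rejections <- vapply(1:15, function(s) {
    coh <- generate_cohort(cohort_config(n_patients = 10000, seed = s,
                                         mortality_target = NULL))
    calibration(coh$true_risk, coh$death30_inpatient)$HL_p < 0.05
  }, TRUE)
  expect_lte(sum(rejections), 4)  # nominal alpha = 0.05 over 15 seeds
})

test_that("cohort CSV and generator config round-trip through disk", {
  coh <- generate_cohort(cohort_config(n_patients = 50, seed = 2,
                                       obstetric_rate = 0.1))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh[, cohort_columns()], path)
  back <- read_cohort(path)
  expect_equal(back$age_years, coh$age_years)
  expect_identical(back$urgency, coh$urgency)
  expect_identical(is.na(back$haemoglobin), is.na(coh$haemoglobin))

  cfg <- cohort_config(n_patients = 40, seed = 8,
                       clinician_model = list(slope = 0.9, bias = 0.5,
                                              noise = 1.2))
  cfg_path <- tempfile(fileext = ".json")
  write_cohort_config(cfg, cfg_path)
  cfg2 <- read_cohort_config(cfg_path)
  expect_equal(cfg2$clinician_model$bias, 0.5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg2)
  expect_equal(c1$true_risk, c2$true_risk)
  expect_identical(c1$subjective_category, c2$subjective_category)
})
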