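# Synthetic perioperative cohort generator.
#
# Emulates the statistical structure of a multicentre inpatient surgical
# cohort: ~1.4% 30-day inpatient mortality, the published marginal mix of
# ASA-PS, urgency, severity and specialty, clinician subjective categories
# that track true risk but overpredict it (additive bias on the logit
# scale), missing preoperative labs concentrated in fitter (low ASA-PS)
# patients, and assessment-method flags with ~21% of episodes aided by an
# objective tool. Only marginal distributions are published; a Gaussian
# copula adds moderate age-ASA and urgency-severity rank correlation by
# default, because fully independent covariates understate the risk
# concentration (and hence the discrimination) seen in real perioperative
# cohorts. Set `dependence = NULL` for independent draws.

.default_mix <- function() {
  list(
    sex             = c(male = 0.472, female = 0.528),
    urgency         = c(elective = 0.533, expedited = 0.146,
                        urgent = 0.292, immediate = 0.028),
    asa_ps          = c("1" = 0.197, "2" = 0.450, "3" = 0.290,
                        "4" = 0.059, "5" = 0.003),
    severity        = c(minor = 0.086, intermediate = 0.200, major = 0.330,
                        xmajor = 0.233, complex = 0.150),
    specialty       = c(gastrointestinal = 0.198, gynae_urology = 0.190,
                        neuro_spinal = 0.053, orthopaedic = 0.299,
                        thoracic_cardiac = 0.046, vascular = 0.030,
                        other = 0.184),
    malignancy      = c(none = 0.880, primary = 0.060, nodal = 0.024,
                        metastatic = 0.036),
    diabetes        = c(none = 0.858, type1 = 0.012, type2_diet = 0.027,
                        type2_oral = 0.069, type2_insulin = 0.034),
    ecg             = c(normal = 0.920, af_60_90 = 0.050,
                        other_abnormal = 0.030),
    blood_loss      = c("<=100" = 0.60, "101-500" = 0.30,
                        "501-999" = 0.07, ">=1000" = 0.03),
    soiling         = c(none = 0.90, serous = 0.05, local_pus = 0.03,
                        free = 0.02),
    procedure_count = c("1" = 0.90, "2" = 0.08, ">2" = 0.02),
    country         = c(UK = 0.85, ANZ = 0.15)
  )
}

.default_comorbidity <- function() {
  c(cad = 0.134, cardiac_failure = 0.039, dementia = 0.030, copd = 0.086,
    cirrhosis = 0.010, renal_disease = 0.017)
}

.normalise_mix <- function(p, var) {
  if (anyNA(p) || any(p < 0) || any(p > 1) || sum(p) <= 0) {
    stop("invalid category frequency vector for variable '", var, "'")
  }
  if (abs(sum(p) - 1) > 0.05) {
    stop("category frequencies for variable '", var,
         "' sum to ", format(sum(p)), ", not 1")
  }
  p / sum(p)
}

#' Configuration of the synthetic cohort generator
#'
#' @param n_patients Number of surgical episodes to generate.
#' @param mortality_target Cohort-level 30-day inpatient mortality the
#'   data-generating mechanism is tuned to (default 0.014).
#' @param covariate_mix Named list of per-variable category frequency
#'   vectors; defaults mirror the published cohort mix (e.g. elective
#'   0.533, ASA I 0.197 ... ASA V 0.003). Vectors are renormalised to sum
#'   to 1; invalid vectors raise an error naming the variable.
#' @param comorbidity_rates Named vector of Bernoulli rates for the
#'   comorbidity flags.
#' @param true_risk_model `risk_model_spec` used as the data-generating
#'   mechanism; defaults to the SORT spec so generated cohorts are
#'   SORT-calibrated by construction. Its intercept is shifted by bisection
#'   so expected cohort mortality hits `mortality_target`.
#' @param clinician_model List with `slope`, `bias` and `noise` (logit
#'   scale) controlling how subjective categories track true risk; the
#'   default positive bias of +0.7 logits with SD-1 noise makes clinicians
#'   overpredict risk while discriminating well.
#' @param objective_tool_usage_rate Probability an episode's risk estimate
#'   was aided by an objective tool (default 0.211).
#' @param lab_missingness_by_asa Probability the preoperative blood panel
#'   is absent, by ASA-PS class (decreasing with ASA-PS: fit patients often
#'   have no preoperative bloods).
#' @param dependence Optional list with elements `age_asa` and/or
#'   `urgency_severity`, Gaussian-copula correlations in [0, 1).
#' @param obstetric_rate,ambulatory_rate,under18_rate,missing_subjective_rate
#'   Rates of ineligible / incomplete records, for exercising the exclusion
#'   pipeline (all default 0: an analysis-ready cohort).
#' @param scale The [subjective_scale()] used for category binning.
#' @param seed Integer seed; a fixed seed yields a bit-identical cohort.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10000, mortality_target = 0.014,
                          covariate_mix = list(),
                          comorbidity_rates = .default_comorbidity(),
                          true_risk_model = sort_spec(),
                          clinician_model = list(slope = 1, bias = 0.7,
                                                 noise = 1.0),
                          objective_tool_usage_rate = 0.211,
                          lab_missingness_by_asa =
                            c(0.35, 0.20, 0.08, 0.03, 0.01),
                          dependence = list(age_asa = 0.5,
                                            urgency_severity = 0.35),
                          obstetric_rate = 0, ambulatory_rate = 0,
                          under18_rate = 0, missing_subjective_rate = 0,
                          scale = subjective_scale(), seed = 1L) {
  stopifnot(n_patients >= 1, length(seed) == 1L)
  probs <- c(mortality_target, objective_tool_usage_rate,
             lab_missingness_by_asa, comorbidity_rates, obstetric_rate,
             ambulatory_rate, under18_rate, missing_subjective_rate)
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all rates/probabilities must lie in [0, 1]")
  }
  stopifnot(length(lab_missingness_by_asa) == 5L)
  mix <- .default_mix()
  unknown <- setdiff(names(covariate_mix), names(mix))
  if (length(unknown)) {
    stop("unknown covariate_mix variable(s): ",
         paste(unknown, collapse = ", "))
  }
  mix[names(covariate_mix)] <- covariate_mix
  mix <- mapply(.normalise_mix, mix, names(mix), SIMPLIFY = FALSE)
  stopifnot(inherits(true_risk_model, "risk_model_spec"),
            all(c("slope", "bias", "noise") %in% names(clinician_model)),
            clinician_model$noise >= 0)
  if (!is.null(dependence)) {
    stopifnot(all(names(dependence) %in% c("age_asa", "urgency_severity")),
              all(unlist(dependence) >= 0), all(unlist(dependence) < 1))
  }
  structure(list(
    n_patients = as.integer(n_patients),
    mortality_target = mortality_target, covariate_mix = mix,
    comorbidity_rates = comorbidity_rates,
    true_risk_model = true_risk_model, clinician_model = clinician_model,
    objective_tool_usage_rate = objective_tool_usage_rate,
    lab_missingness_by_asa = lab_missingness_by_asa,
    dependence = dependence, obstetric_rate = obstetric_rate,
    ambulatory_rate = ambulatory_rate, under18_rate = under18_rate,
    missing_subjective_rate = missing_subjective_rate, scale = scale,
    seed = as.integer(seed)), class = "cohort_config")
}

# draw a categorical vector from a frequency table, optionally via a
# supplied uniform (for copula dependence)
.draw_cat <- function(n, freq, u = NULL) {
  if (is.null(u)) u <- stats::runif(n)
  names(freq)[findInterval(u, cumsum(freq), left.open = TRUE) + 1L]
}

#' True 30-day mortality risk under the data-generating mechanism
#'
#' Imputes normal values for missing labs, evaluates the data-generating
#' `risk_model_spec`, and (optionally) shifts its intercept by a constant
#' found by bisection so the cohort-mean risk equals `mortality_target`.
#'
#' @param cohort A cohort data frame.
#' @param dgm A `risk_model_spec`.
#' @param mortality_target If non-NULL, tune the intercept shift so
#'   `mean(risk)` equals this value (to 1e-10).
#' @return Numeric vector of probabilities in (0, 1); the applied intercept
#'   shift is attached as attribute `"intercept_shift"`.
#' @export
assign_true_risk <- function(cohort, dgm = sort_spec(),
                             mortality_target = NULL) {
  imp <- impute_normal_values(cohort)
  p <- score_model(imp$cohort, dgm)
  lp <- stats::qlogis(p)
  delta <- 0
  if (!is.null(mortality_target)) {
    stopifnot(mortality_target > 0, mortality_target < 1)
    f <- function(d) mean(stats::plogis(lp + d)) - mortality_target
    delta <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
    p <- stats::plogis(lp + delta)
  }
  attr(p, "intercept_shift") <- delta
  p
}

#' Simulate clinician subjective risk categories
#'
#' Models clinician behaviour on the logit scale: the assigned category is
#' the subjective-scale interval containing
#' `expit(bias + slope * logit(true_risk) + N(0, noise))`. With a positive
#' bias, generated categories overpredict observed mortality while
#' remaining highly discriminating. True risks are clipped to
#' [1e-8, 1 - 1e-8] before the logit transform.
#'
#' @param true_risk Probabilities in (0, 1).
#' @param clinician_model List with `slope`, `bias`, `noise` (logit scale).
#' @param scale A [subjective_scale()].
#' @param seed Optional seed for the noise draws.
#' @return Integer categories in 1..6.
#' @export
simulate_subjective <- function(true_risk,
                                clinician_model = list(slope = 1,
                                                       bias = 0.7,
                                                       noise = 1.0),
                                scale = subjective_scale(), seed = NULL) {
  if (anyNA(true_risk) || any(true_risk <= 0 | true_risk >= 1)) {
    stop("`true_risk` must lie strictly inside (0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)
  z <- stats::qlogis(pmin(pmax(true_risk, 1e-8), 1 - 1e-8))
  z2 <- clinician_model$bias + clinician_model$slope * z +
    stats::rnorm(length(z), 0, clinician_model$noise)
  bin_risk(stats::plogis(z2), scale)
}

#' Simulate binary outcomes
#'
#' Independent Bernoulli draws from per-record probabilities.
#'
#' @param probabilities Vector of probabilities in [0, 1].
#' @param seed Optional seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
simulate_outcomes <- function(probabilities, seed = NULL) {
  if (anyNA(probabilities) ||
      any(probabilities < 0 | probabilities > 1)) {
    stop("`probabilities` must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(length(probabilities), 1L, probabilities)
}

#' Generate a synthetic perioperative cohort
#'
#' Draws `n_patients` records per the configured covariate mix, blanks
#' preoperative blood labs with an ASA-dependent probability, computes true
#' risk under the data-generating model (intercept-tuned to the mortality
#' target), simulates 30-day outcomes and clinician subjective categories,
#' and assigns assessment-method flags. Deterministic given the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @return A cohort data frame in the canonical schema, plus a `true_risk`
#'   column (the generator's ground truth). Attributes: `intercept_shift`
#'   (tuned data-generating intercept shift) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  mix <- config$covariate_mix

  # latent uniforms, optionally rank-correlated via a Gaussian copula
  dep <- config$dependence
  gauss_pair <- function(rho) {
    z1 <- stats::rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    list(u1 = stats::pnorm(z1), u2 = stats::pnorm(z2))
  }
  if (!is.null(dep$age_asa)) {
    aa <- gauss_pair(dep$age_asa); u_age <- aa$u1; u_asa <- aa$u2
  } else {
    u_age <- stats::runif(n); u_asa <- stats::runif(n)
  }
  if (!is.null(dep$urgency_severity)) {
    us <- gauss_pair(dep$urgency_severity); u_urg <- us$u1; u_sev <- us$u2
  } else {
    u_urg <- stats::runif(n); u_sev <- stats::runif(n)
  }

  age <- round(pmin(pmax(stats::qnorm(u_age, 62, 19), 18), 95))
  asa <- as.integer(.draw_cat(n, mix$asa_ps, u_asa))
  urgency <- .draw_cat(n, mix$urgency, u_urg)
  severity <- .draw_cat(n, mix$severity, u_sev)

  cohort <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    age_years = age,
    sex = .draw_cat(n, mix$sex),
    asa_ps = asa,
    urgency = urgency,
    severity = severity,
    specialty = .draw_cat(n, mix$specialty),
    malignancy = .draw_cat(n, mix$malignancy),
    stringsAsFactors = FALSE)
  for (fl in names(config$comorbidity_rates)) {
    cohort[[fl]] <- stats::runif(n) < config$comorbidity_rates[[fl]]
  }
  cohort$diabetes <- .draw_cat(n, mix$diabetes)

  cohort$systolic_bp <- round(pmin(pmax(stats::rnorm(n, 130, 20), 70), 220))
  cohort$pulse <- round(pmin(pmax(stats::rnorm(n, 78, 14), 35), 160))
  cohort$gcs <- ifelse(stats::runif(n) < 0.99, 15L,
                       sample(12:14, n, replace = TRUE))
  cohort$haemoglobin <- round(pmin(pmax(stats::rnorm(n, 13.5, 1.8), 6), 19),
                              1)
  cohort$wbc <- round(pmin(pmax(stats::rnorm(n, 8, 2.5), 1.5), 30), 1)
  cohort$urea <- round(pmin(stats::rlnorm(n, log(5), 0.45), 40), 1)
  cohort$sodium <- round(pmin(pmax(stats::rnorm(n, 139, 3.2), 118), 152))
  cohort$potassium <- round(pmin(pmax(stats::rnorm(n, 4.2, 0.45), 2.4),
                                 6.8), 1)
  cohort$ecg <- .draw_cat(n, mix$ecg)
  cohort$blood_loss <- .draw_cat(n, mix$blood_loss)
  cohort$soiling <- .draw_cat(n, mix$soiling)
  cohort$procedure_count <- .draw_cat(n, mix$procedure_count)

  # eligibility flags; under-18 records get an age of 16-17
  cohort$obstetric <- stats::runif(n) < config$obstetric_rate
  cohort$ambulatory <- stats::runif(n) < config$ambulatory_rate
  cohort$under18 <- stats::runif(n) < config$under18_rate
  cohort$age_years[cohort$under18] <- sample(16:17,
                                             sum(cohort$under18),
                                             replace = TRUE)
  cohort$country <- .draw_cat(n, mix$country)

  # blood panel missing as a block, more often in fitter patients
  p_miss <- config$lab_missingness_by_asa[cohort$asa_ps]
  miss <- stats::runif(n) < p_miss
  for (v in c("haemoglobin", "wbc", "urea", "sodium", "potassium")) {
    cohort[[v]][miss] <- NA
  }

  risk <- assign_true_risk(cohort, config$true_risk_model,
                           config$mortality_target)
  cohort$true_risk <- as.numeric(risk)
  cohort$death30_inpatient <- simulate_outcomes(cohort$true_risk)
  cohort$subjective_category <- simulate_subjective(
    cohort$true_risk, config$clinician_model, config$scale)
  if (config$missing_subjective_rate > 0) {
    blank <- stats::runif(n) < config$missing_subjective_rate
    cohort$subjective_category[blank] <- NA_integer_
  }

  # assessment-method flags: clinical judgement and/or ASA-PS nearly
  # always; a minority of estimates aided by an objective tool
  cohort$method_clinical <- stats::runif(n) < 0.887
  cohort$method_asa <- stats::runif(n) < 0.381
  tool <- stats::runif(n) < config$objective_tool_usage_rate
  r <- config$objective_tool_usage_rate
  cohort$method_sort <- tool & (stats::runif(n) < 0.033 / r)
  cohort$method_ppossum <- tool & (stats::runif(n) < 0.062 / r)
  cohort$method_srs <- tool & (stats::runif(n) < 0.014 / r)
  cohort$method_other_tool <- tool &
    !(cohort$method_sort | cohort$method_ppossum | cohort$method_srs)
  # records with neither judgement nor ASA nor tool: judgement by default
  none <- !(cohort$method_clinical | cohort$method_asa | tool)
  cohort$method_clinical[none] <- TRUE

  cohort <- cohort[, c(cohort_columns(), "true_risk")]
  attr(cohort, "intercept_shift") <- attr(risk, "intercept_shift")
  attr(cohort, "config") <- config
  validate_cohort(cohort)
}

#' Read / write a cohort-generator configuration as JSON
#'
#' Serializes the full [cohort_config()], embedding the data-generating
#' model spec, so a cohort can be regenerated exactly from config + seed.
#'
#' @param config A `cohort_config`.
#' @param path File path.
#' @return `read_cohort_config()` returns a validated `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$true_risk_model <- .spec_to_list(config$true_risk_model)
  out$scale <- list(top_midpoint = config$scale$midpoint[6])
  out$covariate_mix <- lapply(out$covariate_mix, as.list)
  out$comorbidity_rates <- as.list(out$comorbidity_rates)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cohort_config(
    n_patients = raw$n_patients,
    mortality_target = raw$mortality_target,
    covariate_mix = lapply(raw$covariate_mix, function(x)
      unlist(lapply(x, as.numeric))),
    comorbidity_rates = unlist(lapply(raw$comorbidity_rates, as.numeric)),
    true_risk_model = .spec_from_list(raw$true_risk_model, context = path),
    clinician_model = lapply(raw$clinician_model, as.numeric),
    objective_tool_usage_rate = raw$objective_tool_usage_rate,
    lab_missingness_by_asa = as.numeric(unlist(raw$lab_missingness_by_asa)),
    dependence = if (length(raw$dependence))
      lapply(raw$dependence, as.numeric) else NULL,
    obstetric_rate = raw$obstetric_rate,
    ambulatory_rate = raw$ambulatory_rate,
    under18_rate = raw$under18_rate,
    missing_subjective_rate = raw$missing_subjective_rate,
    scale = subjective_scale(top_midpoint = raw$scale$top_midpoint),
    seed = raw$seed)
}
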