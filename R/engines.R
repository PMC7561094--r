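# Scoring engine: normal-value imputation, feature derivation, POSSUM
# sub-scores and evaluation of a risk_model_spec on a cohort table.

#' Normal-value defaults for missing preoperative physiology
#'
#' Fit patients frequently reach theatre without preoperative blood tests,
#' so missing physiology/labs are imputed at normal values before scoring —
#' the value a clinician would assume when a test was not indicated. Each
#' default sits in the minimum-score (no-abnormality) band of the
#' corresponding POSSUM physiology item.
#'
#' @param ... Named overrides of individual defaults, e.g. `urea = 6`.
#' @return Named list of defaults (class `normal_value_table`): sodium 140
#'   mmol/L, potassium 4.0 mmol/L, urea 5.0 mmol/L, haemoglobin 14.0 g/dL,
#'   WBC 8.0 x10^9/L, pulse 75 bpm, systolic BP 120 mmHg, GCS 15,
#'   ECG "normal".
#' @export
normal_value_table <- function(...) {
  tab <- list(systolic_bp = 120, pulse = 75, gcs = 15, haemoglobin = 14.0,
              wbc = 8.0, urea = 5.0, sodium = 140, potassium = 4.0,
              ecg = "normal")
  dots <- list(...)
  bad <- setdiff(names(dots), names(tab))
  if (length(bad)) stop("unknown lab field(s): ", paste(bad, collapse = ", "))
  tab[names(dots)] <- dots
  structure(tab, class = "normal_value_table")
}

#' Impute normal values for missing physiology/labs
#'
#' Replaces every missing physiology/lab field with its configured normal
#' default and leaves observed values untouched. Per-field logical flags are
#' returned for audit, so downstream sensitivity analyses can restrict to
#' fully observed records.
#'
#' @param cohort A cohort data frame (canonical schema).
#' @param table A [normal_value_table()].
#' @return A list with elements `cohort` (imputed table) and `flags`
#'   (logical data frame, one column per lab field, TRUE where imputed).
#' @export
impute_normal_values <- function(cohort, table = normal_value_table()) {
  stopifnot(is.data.frame(cohort), inherits(table, "normal_value_table"))
  flags <- as.data.frame(lapply(.surgrisk_lab_fields, function(v) {
    is.na(cohort[[v]])
  }), col.names = .surgrisk_lab_fields)
  for (v in .surgrisk_lab_fields) {
    miss <- flags[[v]]
    if (any(miss)) cohort[[v]][miss] <- table[[v]]
  }
  list(cohort = cohort, flags = flags)
}

# first-match band lookup for numeric POSSUM items; bands are lists of
# {lo?, hi?, score} with missing bounds open. If a value falls in a
# typographical gap between published bands, the nearest band wins.
.band_score <- function(x, bands) {
  lo <- vapply(bands, function(b) if (is.null(b$lo)) -Inf else b$lo, 0)
  hi <- vapply(bands, function(b) if (is.null(b$hi)) Inf else b$hi, 0)
  sc <- vapply(bands, function(b) as.numeric(b$score), 0)
  out <- rep(NA_real_, length(x))
  for (i in seq_along(bands)) {
    hit <- is.na(out) & !is.na(x) & x >= lo[i] & x <= hi[i]
    out[hit] <- sc[i]
  }
  gap <- is.na(out) & !is.na(x)
  if (any(gap)) {
    for (j in which(gap)) {
      d <- pmax(lo - x[j], x[j] - hi, 0)
      out[j] <- sc[which.min(d)]
    }
  }
  out
}

.item_score <- function(cohort, item) {
  src <- item$source
  x <- switch(src,
    cardiac_signs = ifelse(cohort$cardiac_failure, "oedema",
                           ifelse(cohort$cad, "therapy", "none")),
    respiratory_signs = ifelse(cohort$copd, "mild", "none"),
    cohort[[src]])
  if (is.null(x)) stop("POSSUM item source not found: ", src)
  if (identical(item$type, "numeric")) {
    if (anyNA(x)) stop("missing values in POSSUM item '", item$name,
                       "': impute normal values first")
    .band_score(as.numeric(x), item$bands)
  } else {
    scores <- unlist(item$scores)
    if (anyNA(x)) stop("missing values in POSSUM item '", item$name,
                       "': impute normal values first")
    unknown <- setdiff(unique(x), names(scores))
    if (length(unknown)) {
      stop("unmapped level(s) in POSSUM item '", item$name, "': ",
           paste(unknown, collapse = ", "))
    }
    as.numeric(scores[match(x, names(scores))])
  }
}

#' POSSUM physiological and operative-severity sub-scores
#'
#' Computes the 12-item physiological and 6-item operative integer
#' sub-scores (each item scored 1/2/4/8) from a cohort table, using the
#' banding tables carried in the model spec config, so band edits never
#' require code changes.
#'
#' @param cohort A cohort data frame with labs imputed/complete.
#' @param spec A `risk_model_spec` carrying `possum_bands` (e.g.
#'   [ppossum_spec()]).
#' @return Data frame with integer columns `physiology` and `operative`.
#' @export
possum_scores <- function(cohort, spec = ppossum_spec()) {
  stopifnot(inherits(spec, "risk_model_spec"))
  if (is.null(spec$possum_bands)) {
    stop("spec '", spec$name, "' carries no POSSUM banding tables")
  }
  score_side <- function(items) {
    Reduce(`+`, lapply(items, function(it) .item_score(cohort, it)))
  }
  data.frame(
    physiology = score_side(spec$possum_bands$physiology),
    operative  = score_side(spec$possum_bands$operative))
}

# derive the feature columns a spec's variable_map references
.build_features <- function(cohort, spec) {
  needed <- unique(unlist(spec$variable_map, use.names = FALSE))
  feats <- list()
  urg <- cohort$urgency
  if (!is.null(spec$urgency_map)) {
    for (from in names(spec$urgency_map)) {
      urg[urg == from] <- spec$urgency_map[[from]]
    }
  }
  for (f in needed) {
    val <- switch(f,
      urgency = urg,
      asa_class = as.character(cohort$asa_ps),
      age_band = cut(cohort$age_years, c(-Inf, 64, 79, Inf),
                     labels = c("18-64", "65-79", "80+")),
      highrisk_specialty = ifelse(
        cohort$specialty %in% c("gastrointestinal", "thoracic_cardiac",
                                "vascular"), "yes", "no"),
      severity_xmajor_complex = ifelse(
        cohort$severity %in% c("xmajor", "complex"), "yes", "no"),
      malignancy_any = ifelse(cohort$malignancy == "none", "no", "yes"),
      possum_physiology = possum_scores(cohort, spec)$physiology,
      possum_operative = possum_scores(cohort, spec)$operative,
      srs_score = {
        m <- spec$srs_maps
        if (is.null(m)) stop("spec '", spec$name, "' needs srs_maps")
        cepod <- unlist(m$cepod)[cohort$urgency]
        bupa <- unlist(m$bupa)[cohort$severity]
        as.numeric(cepod) + as.numeric(bupa) + cohort$asa_ps
      },
      cohort[[f]])
    if (is.null(val)) stop("cannot derive feature: ", f)
    if (is.factor(val)) val <- as.character(val)
    feats[[f]] <- val
  }
  feats
}

#' Evaluate a risk model on a cohort
#'
#' Computes predicted 30-day mortality risk per record as the inverse logit
#' of the spec's linear predictor: intercept plus the coefficient of every
#' matched (variable, level) dummy plus coefficient-times-value for
#' continuous terms (e.g. the POSSUM integer sub-scores). Records must be
#' complete for the spec's variables; run [impute_normal_values()] first.
#'
#' @param cohort A cohort data frame.
#' @param spec A `risk_model_spec`.
#' @param percent If TRUE return risk in percent (0--100) instead of a
#'   probability.
#' @return Numeric vector of predicted risks, strictly inside (0, 1) (or
#'   (0, 100) with `percent = TRUE`).
#' @export
score_model <- function(cohort, spec, percent = FALSE) {
  stopifnot(is.data.frame(cohort), inherits(spec, "risk_model_spec"))
  feats <- .build_features(cohort, spec)
  lp <- rep(spec$intercept, nrow(cohort))
  tr <- spec$terms
  for (i in seq_len(nrow(tr))) {
    fname <- spec$variable_map[[tr$variable[i]]]
    x <- feats[[fname]]
    if (is.na(tr$level[i])) {
      if (anyNA(x)) stop("missing values in continuous variable '",
                         tr$variable[i], "'")
      lp <- lp + tr$coefficient[i] * x
    } else {
      if (anyNA(x)) {
        bad <- cohort$patient_id[which(is.na(x))[1]]
        stop(sprintf("record %s: missing value for variable '%s'",
                     bad, tr$variable[i]))
      }
      lp <- lp + tr$coefficient[i] * (x == tr$level[i])
    }
  }
  # categorical record values must be resolvable against the schema levels;
  # unknown levels were already rejected by validate_cohort / POSSUM maps
  p <- stats::plogis(lp)
  if (percent) 100 * p else p
}

#' Score a cohort with the three shipped objective models
#'
#' Convenience wrapper: imputes normal values, then appends
#' `sort_risk_pct`, `ppossum_risk_pct` and `srs_risk_pct` columns (percent
#' scale) plus one `imputed_any_lab` audit flag.
#'
#' @param cohort A cohort data frame.
#' @param specs Named list of `risk_model_spec`s; names become column
#'   prefixes.
#' @param table Normal-value table used for imputation.
#' @return The cohort with risk columns appended.
#' @export
score_cohort <- function(cohort,
                         specs = list(sort = sort_spec(),
                                      ppossum = ppossum_spec(),
                                      srs = srs_spec()),
                         table = normal_value_table()) {
  imp <- impute_normal_values(cohort, table)
  for (nm in names(specs)) {
    cohort[[paste0(nm, "_risk_pct")]] <-
      score_model(imp$cohort, specs[[nm]], percent = TRUE)
  }
  cohort$imputed_any_lab <- Reduce(`|`, imp$flags)
  cohort
}
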