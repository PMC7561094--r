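# Study pipeline: exclusion flow, scoring, and the three inferential
# analyses (external validation of the objective models; evaluation of
# subjective assessment; the combined subjective + SORT model with
# bootstrap internal validation, NRI, decision curves and the
# conditional-probability surface).

#' Study configuration
#'
#' @param B Bootstrap replicates for optimism correction (default 1000).
#' @param seed Master seed; per-stage streams are derived from it.
#' @param dca_grid Decision-curve threshold grid (default 0.1%--50% in
#'   0.1% steps).
#' @param surface_grid SORT grid (percent) for the combined-model surface
#'   (default 0--50% in 0.5% steps).
#' @param min_events Minimum events required to run a subgroup analysis.
#' @param scale Subjective scale used for midpoints.
#' @param specs Named list of objective model specs; must contain `sort`.
#' @return List of class `study_config`.
#' @export
study_config <- function(B = 1000, seed = 1L,
                         dca_grid = seq(0.001, 0.5, by = 0.001),
                         surface_grid = seq(0, 50, by = 0.5),
                         min_events = 20,
                         scale = subjective_scale(),
                         specs = list(sort = sort_spec(),
                                      ppossum = ppossum_spec(),
                                      srs = srs_spec())) {
  stopifnot(B >= 1, "sort" %in% names(specs))
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 dca_grid = dca_grid, surface_grid = surface_grid,
                 min_events = min_events, scale = scale, specs = specs),
            class = "study_config")
}

#' Apply the study exclusion flow
#'
#' Rules are applied in a fixed, logged order: (1) eligibility flags —
#' obstetric, under-18, ambulatory episodes removed; (2) complete-case
#' removal on the required analysis variables (after normal-value
#' imputation of labs, which therefore never triggers exclusion); this
#' yields the external-validation cohort. (3) Episodes whose risk estimate
#' was aided by an objective tool are then carved out, yielding the
#' subjective-assessment-only subcohort used for the second and third
#' analyses.
#'
#' @param raw A raw cohort data frame (canonical schema).
#' @return List with `validation_cohort`, `subjective_cohort`, and `log`
#'   (an `exclusion_log`: per-rule removal counts with before/after totals
#'   whose arithmetic always balances).
#' @export
apply_exclusions <- function(raw) {
  validate_cohort(raw)
  n0 <- nrow(raw)
  counts <- c(obstetric = sum(raw$obstetric),
              under18 = sum(!raw$obstetric & raw$under18),
              ambulatory = sum(!raw$obstetric & !raw$under18 &
                                 raw$ambulatory))
  eligible <- raw[!(raw$obstetric | raw$under18 | raw$ambulatory), ,
                  drop = FALSE]
  required <- c("age_years", "sex", "asa_ps", "urgency", "severity",
                "specialty", "malignancy", "subjective_category",
                "death30_inpatient")
  complete <- stats::complete.cases(eligible[, required])
  counts["incomplete"] <- sum(!complete)
  validation <- eligible[complete, , drop = FALSE]
  tool <- validation$method_sort | validation$method_ppossum |
    validation$method_srs | validation$method_other_tool
  counts["tool_assisted"] <- sum(tool)
  subjective <- validation[!tool, , drop = FALSE]
  log <- structure(list(
    before = n0,
    removed = as.list(counts),
    after_eligibility = nrow(eligible),
    after_complete_case = nrow(validation),
    after_tool_carveout = nrow(subjective)), class = "exclusion_log")
  stopifnot(log$before - counts[["obstetric"]] - counts[["under18"]] -
              counts[["ambulatory"]] == log$after_eligibility,
            log$after_eligibility - counts[["incomplete"]] ==
              log$after_complete_case,
            log$after_complete_case - counts[["tool_assisted"]] ==
              log$after_tool_carveout)
  list(validation_cohort = validation, subjective_cohort = subjective,
       log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion flow:\n")
  cat(sprintf("  raw episodes:                 %d\n", x$before))
  cat(sprintf("  - obstetric:                  %d\n", x$removed$obstetric))
  cat(sprintf("  - under 18:                   %d\n", x$removed$under18))
  cat(sprintf("  - ambulatory:                 %d\n", x$removed$ambulatory))
  cat(sprintf("  eligible:                     %d\n", x$after_eligibility))
  cat(sprintf("  - incomplete required fields: %d\n", x$removed$incomplete))
  cat(sprintf("  external-validation cohort:   %d\n",
              x$after_complete_case))
  cat(sprintf("  - objective-tool assisted:    %d\n",
              x$removed$tool_assisted))
  cat(sprintf("  subjective-only subcohort:    %d\n",
              x$after_tool_carveout))
  invisible(x)
}

#' Cohort demographics table
#'
#' Counts and percentages of the key covariates stratified by 30-day
#' mortality, in the conventional baseline-table layout.
#'
#' @param cohort A cohort data frame.
#' @return Data frame with columns `variable`, `level`, `overall_n`,
#'   `overall_pct`, `died_n`, `died_pct`.
#' @export
cohort_summary <- function(cohort) {
  died <- cohort$death30_inpatient == 1L
  one_var <- function(var) {
    x <- cohort[[var]]
    lv <- if (var %in% names(.surgrisk_levels)) .surgrisk_levels[[var]]
          else sort(unique(x))
    do.call(rbind, lapply(lv, function(l) {
      data.frame(variable = var, level = as.character(l),
                 overall_n = sum(x == l),
                 overall_pct = round(100 * mean(x == l), 1),
                 died_n = sum(x == l & died),
                 died_pct = round(100 * sum(x == l & died) /
                                    max(1, sum(died)), 1),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(
    c("sex", "urgency", "asa_ps", "severity", "specialty", "malignancy"),
    one_var))
  rbind(data.frame(variable = "cohort", level = "all",
                   overall_n = nrow(cohort), overall_pct = 100,
                   died_n = sum(died),
                   died_pct = round(100 * mean(died), 2),
                   stringsAsFactors = FALSE),
        out)
}

#' Assessment-method usage table
#'
#' @param cohort A cohort data frame.
#' @return Data frame of counts and percentages per assessment-method
#'   flag; flags are not mutually exclusive so percentages can exceed 100
#'   in total.
#' @export
method_usage <- function(cohort) {
  flags <- .surgrisk_method_fields
  data.frame(method = flags,
             n = vapply(flags, function(f) sum(cohort[[f]]), 0L),
             pct = round(vapply(flags, function(f)
               100 * mean(cohort[[f]]), 0), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

.auroc_of_combined <- function(model, data) {
  auroc(predict_combined(data$subjective_category, data$sort_risk_pct,
                         model$coefs),
        data$death30_inpatient)$auroc
}

#' Run the full study analysis
#'
#' Orchestrates the three inferential analyses on a raw cohort:
#' \enumerate{
#'   \item External validation of the objective models on the full
#'     validation cohort: calibration + Hosmer--Lemeshow, AUROC, and all
#'     pairwise DeLong comparisons.
#'   \item Evaluation of subjective assessment on the subjective-only
#'     subcohort: midpoint calibration, ordinal polygon ROC, DeLong
#'     SORT-vs-subjective, and continuous NRI (subjective entering as its
#'     interval midpoint probability).
#'   \item The combined subjective + SORT model: maximum-likelihood fit,
#'     bootstrap optimism-corrected AUROC, a comparison table (AUROC + CI
#'     + DeLong p, NRI + CI + p against the subjective reference),
#'     decision curves for subjective, SORT, P-POSSUM, SRS and the
#'     combined model, and the conditional-probability surface over the
#'     configured SORT grid.
#' }
#'
#' @param raw A raw cohort data frame.
#' @param config A [study_config()].
#' @return Object of class `study_report`.
#' @export
run_study <- function(raw, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  ex <- apply_exclusions(raw)
  validation <- score_cohort(ex$validation_cohort, config$specs)
  subj <- score_cohort(ex$subjective_cohort, config$specs)

  # analysis 1: external validation of the objective models
  obs_v <- validation$death30_inpatient
  external <- lapply(names(config$specs), function(nm) {
    pred <- validation[[paste0(nm, "_risk_pct")]] / 100
    list(model = nm, calibration = calibration(pred, obs_v),
         roc = auroc(pred, obs_v))
  })
  names(external) <- names(config$specs)
  pairs <- utils::combn(names(config$specs), 2, simplify = FALSE)
  delong_external <- lapply(pairs, function(pr) {
    d <- delong_compare(validation[[paste0(pr[1], "_risk_pct")]],
                        validation[[paste0(pr[2], "_risk_pct")]], obs_v)
    list(pair = pr, test = d)
  })

  # analysis 2: subjective assessment on the subjective-only subcohort
  obs_s <- subj$death30_inpatient
  cat_s <- subj$subjective_category
  mid_p <- midpoint_of(cat_s, config$scale) / 100
  subj_block <- list(
    calibration = calibration(mid_p, obs_s, n_bins = 6),
    roc = auroc_ordinal(cat_s, obs_s),
    delong_vs_sort = delong_compare(cat_s, subj$sort_risk_pct, obs_s),
    nri_sort_vs_subjective = continuous_nri(mid_p,
                                            subj$sort_risk_pct / 100,
                                            obs_s))

  # analysis 3: combined model with optimism correction
  model <- fit_combined(subj)
  optimism <- bootstrap_optimism(
    subj, fit_combined, .auroc_of_combined, B = config$B,
    seed = config$seed + 1L, metric_name = "AUROC")
  pred_comb <- predict(model, subj)
  roc_subj <- subj_block$roc
  roc_sort_s <- auroc(subj$sort_risk_pct, obs_s)
  roc_comb <- auroc(pred_comb, obs_s)
  comparison <- data.frame(
    model = c("subjective", "sort", "combined"),
    auroc = c(roc_subj$auroc, roc_sort_s$auroc, roc_comb$auroc),
    auroc_corrected = c(NA, NA, optimism$corrected),
    ci_lower = c(roc_subj$ci95[1], roc_sort_s$ci95[1], roc_comb$ci95[1]),
    ci_upper = c(roc_subj$ci95[2], roc_sort_s$ci95[2], roc_comb$ci95[2]),
    delong_p = c(NA,
                 delong_compare(subj$sort_risk_pct, cat_s, obs_s)$p,
                 delong_compare(pred_comb, cat_s, obs_s)$p),
    nri = NA_real_, nri_lower = NA_real_, nri_upper = NA_real_,
    nri_p = NA_real_, stringsAsFactors = FALSE)
  nri_sort <- continuous_nri(mid_p, subj$sort_risk_pct / 100, obs_s)
  nri_comb <- continuous_nri(mid_p, pred_comb, obs_s)
  comparison[2, c("nri", "nri_lower", "nri_upper", "nri_p")] <-
    c(nri_sort$nri_total, nri_sort$ci95, nri_sort$p)
  comparison[3, c("nri", "nri_lower", "nri_upper", "nri_p")] <-
    c(nri_comb$nri_total, nri_comb$ci95, nri_comb$p)

  dca <- lapply(list(subjective = mid_p,
                     sort = subj$sort_risk_pct / 100,
                     ppossum = subj$ppossum_risk_pct / 100,
                     srs = subj$srs_risk_pct / 100,
                     combined = pred_comb),
                decision_curve, obs = obs_s, grid = config$dca_grid)

  structure(list(
    seed = config$seed,
    exclusions = ex$log,
    table1 = cohort_summary(validation),
    table2 = method_usage(validation),
    external = external,
    delong_external = delong_external,
    subjective = subj_block,
    combined = list(model = model, optimism = optimism,
                    comparison = comparison,
                    surface = combined_surface(model$coefs,
                                               config$surface_grid)),
    dca = dca,
    n_validation = nrow(validation),
    n_subjective = nrow(subj)), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Perioperative risk study report\n")
  print(x$exclusions)
  mort <- x$table1$died_pct[x$table1$variable == "cohort"]
  cat(sprintf("\n30-day inpatient mortality (validation cohort): %.2f%%\n",
              mort))
  cat("\nExternal validation (objective models):\n")
  for (e in x$external) {
    cat(sprintf("  %-8s AUROC %.3f (%.3f-%.3f); HL chi-sq %.1f, p %.3g\n",
                e$model, e$roc$auroc, e$roc$ci95[1], e$roc$ci95[2],
                e$calibration$HL_statistic, e$calibration$HL_p))
  }
  cat(sprintf("\nSubjective assessment (n = %d): polygon AUROC %.3f\n",
              x$n_subjective, x$subjective$roc$auroc))
  cat("\nCombined subjective + SORT model:\n")
  print(x$combined$optimism)
  cat("\nComparison table:\n")
  print(round_df(x$combined$comparison, 4))
  invisible(x)
}

# round only numeric columns (print helper)
round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Re-run the study on a subgroup
#'
#' Applies the full pipeline to the subset of raw episodes selected by a
#' predicate (sensitivity analyses: country, high-risk criteria, complete
#' P-POSSUM records, specialty subgroups). Refuses subgroups with fewer
#' events than `config$min_events`.
#'
#' @param raw A raw cohort data frame.
#' @param predicate Function mapping the cohort data frame to a logical
#'   selection vector.
#' @param config A [study_config()].
#' @param description Label stored in the report.
#' @return A `study_report` with a `subgroup` attribute.
#' @export
run_subgroup <- function(raw, predicate, config = study_config(),
                         description = deparse(substitute(predicate))) {
  sel <- predicate(raw)
  stopifnot(is.logical(sel), length(sel) == nrow(raw))
  sub <- raw[sel & !is.na(sel), , drop = FALSE]
  if (nrow(sub) == 0L) stop("subgroup predicate matched zero rows")
  ev <- sum(sub$death30_inpatient, na.rm = TRUE)
  if (ev < config$min_events) {
    stop("subgroup has ", ev, " events; fewer than the required ",
         config$min_events)
  }
  rep <- run_study(sub, config)
  attr(rep, "subgroup") <- description
  rep
}
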