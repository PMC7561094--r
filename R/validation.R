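# Prognostic-model validation statistics: calibration + Hosmer-Lemeshow,
# ROC/AUROC (continuous and ordinal polygon), DeLong's correlated-ROC test,
# continuous net reclassification improvement, decision-curve net benefit,
# and bootstrap optimism correction.

.check_binary <- function(obs) {
  obs <- as.integer(obs)
  if (anyNA(obs) || !all(obs %in% c(0L, 1L))) {
    stop("`obs` must be binary 0/1 with no missing values")
  }
  if (length(unique(obs)) < 2L) {
    stop("both outcome classes must be present")
  }
  obs
}

# Wilson score interval for a binomial proportion
.wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(0, ctr - hw), upper = pmin(1, ctr + hw))
}

#' Calibration binning and the Hosmer--Lemeshow test
#'
#' Bins predictions into deciles of predicted risk (ties kept together:
#' duplicated quantile breaks are merged, so fewer than `n_bins` bins can
#' result), and within each bin reports mean predicted risk, observed death
#' proportion with a Wilson 95% CI, and counts. The Hosmer--Lemeshow
#' statistic is \eqn{\sum_g (O_g-E_g)^2 / (E_g (1 - E_g/n_g))} with
#' `df = bins - 2`; `df` is reported so the p-value can be re-derived under
#' other conventions. A nonparametric smoothed observed-vs-predicted curve
#' (lowess, span 2/3) accompanies the bins.
#'
#' @param pred Predicted probabilities in [0, 1].
#' @param obs Binary outcomes.
#' @param n_bins Number of risk bins (default 10, deciles).
#' @return Object of class `calibration_result`: list with `bins` (data
#'   frame), `smooth` (data frame `pred`, `obs_smoothed`), `HL_statistic`,
#'   `HL_df`, `HL_p`, `n`, and `degenerate` flag (TRUE when all predictions
#'   are identical and the test is undefined).
#' @export
calibration <- function(pred, obs, n_bins = 10) {
  obs <- .check_binary(obs)
  stopifnot(length(pred) == length(obs), n_bins >= 2)
  if (anyNA(pred) || any(pred < 0 | pred > 1)) {
    stop("`pred` must be probabilities in [0, 1]")
  }
  if (length(pred) < n_bins) stop("need at least `n_bins` observations")
  breaks <- unique(stats::quantile(pred, probs = seq(0, 1, length.out =
                                                       n_bins + 1)))
  degenerate <- length(breaks) < 3L
  grp <- if (degenerate) factor(rep(1L, length(pred))) else
    cut(pred, breaks, include.lowest = TRUE)
  n_g <- as.vector(table(grp))
  O <- as.vector(tapply(obs, grp, sum))
  E <- as.vector(tapply(pred, grp, sum))
  mean_pred <- as.vector(tapply(pred, grp, mean))
  prop <- O / n_g
  ci <- .wilson_ci(O, n_g)
  bins <- data.frame(bin = seq_along(n_g), n = n_g, deaths = O,
                     mean_pred = mean_pred, obs_prop = prop,
                     ci_lower = ci[, "lower"], ci_upper = ci[, "upper"])
  if (degenerate || length(n_g) < 3L) {
    HL <- NA_real_; df <- NA_integer_; p <- NA_real_
  } else {
    HL <- sum((O - E)^2 / (E * (1 - E / n_g)))
    df <- length(n_g) - 2L
    p <- stats::pchisq(HL, df, lower.tail = FALSE)
  }
  sm <- stats::lowess(pred, obs, f = 2 / 3)
  structure(list(bins = bins,
                 smooth = data.frame(pred = sm$x, obs_smoothed = sm$y),
                 HL_statistic = HL, HL_df = df, HL_p = p,
                 n = length(obs), degenerate = degenerate),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration over %d bin(s), n = %d\n", nrow(x$bins), x$n))
  print(round(x$bins, 4))
  if (x$degenerate) {
    cat("Degenerate predictor (all predictions identical): HL undefined\n")
  } else if (!is.na(x$HL_statistic)) {
    cat(sprintf("Hosmer-Lemeshow chi-sq = %.2f, df = %d, p = %.3g\n",
                x$HL_statistic, x$HL_df, x$HL_p))
  }
  invisible(x)
}

# DeLong placements: list(auc, v10 (cases), v01 (controls))
.delong_placements <- function(pred, obs) {
  x <- pred[obs == 1L]; y <- pred[obs == 0L]
  n1 <- length(x); n0 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (r[seq_len(n1)] - rx) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - ry) / n1
  list(auc = (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0),
       v10 = v10, v01 = v01)
}

.roc_points <- function(pred, obs) {
  # one operating point per distinct predictor value (threshold = value,
  # positive if pred >= threshold), plus the (0,0) endpoint; the final
  # tie-group point is (1,1)
  o <- order(pred, decreasing = TRUE)
  p <- pred[o]; y <- obs[o]
  n1 <- sum(y == 1L); n0 <- length(y) - n1
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(p, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
}

.trapezoid <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}

.auroc_impl <- function(pred, obs, predictor_kind, level = 0.95) {
  obs <- .check_binary(obs)
  stopifnot(length(pred) == length(obs))
  if (anyNA(pred)) stop("`pred` must not contain missing values")
  pl <- .delong_placements(pred, obs)
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  pts <- .roc_points(pred, obs)
  area <- .trapezoid(pts$fpr, pts$tpr)
  if (abs(area - pl$auc) > 1e-12) {
    stop("internal inconsistency: trapezoid area != Mann-Whitney AUROC")
  }
  structure(list(auroc = pl$auc, variance = v,
                 ci95 = c(lower = max(0, pl$auc - z * sqrt(v)),
                          upper = min(1, pl$auc + z * sqrt(v))),
                 points = pts, predictor_kind = predictor_kind,
                 n_events = n1, n_nonevents = n0),
            class = "roc_result")
}

#' AUROC with DeLong variance
#'
#' Area under the ROC curve computed as the Mann--Whitney concordance
#' statistic with ties counted 1/2, which equals the trapezoidal area under
#' the empirical ROC points (asserted internally). The variance is the
#' DeLong placement estimator; the 95% CI uses the normal approximation.
#'
#' @param pred Numeric risk predictions (any monotone score).
#' @param obs Binary outcomes (both classes required).
#' @return Object of class `roc_result`: `auroc`, `variance`, `ci95`,
#'   `points` (FPR/TPR operating points including (0,0) and (1,1)),
#'   `predictor_kind`, and class counts.
#' @export
auroc <- function(pred, obs) .auroc_impl(pred, obs, "continuous")

#' Ordinal (polygon) AUROC
#'
#' ROC analysis for an ordered categorical predictor (e.g. the 6-category
#' subjective scale): sensitivity and specificity are computed at each
#' category threshold, giving one operating point per category, and the
#' area is the trapezoid over the resulting polygon — equal to the
#' Mann--Whitney statistic with ties 1/2 applied to category ranks.
#'
#' @param categories Integer ordinal predictor (at least 2 distinct values).
#' @param obs Binary outcomes.
#' @return An object of class `roc_result` with
#'   `predictor_kind = "ordinal"`.
#' @export
auroc_ordinal <- function(categories, obs) {
  categories <- as.integer(categories)
  if (length(unique(categories)) < 2L) {
    stop("need at least 2 distinct categories")
  }
  .auroc_impl(categories, obs, "ordinal")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (95%% CI %.3f-%.3f), %s predictor, %d/%d events\n",
              x$auroc, x$ci95["lower"], x$ci95["upper"], x$predictor_kind,
              x$n_events, x$n_events + x$n_nonevents))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l", lwd = 2,
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("ROC (AUROC = %.3f)", x$auroc), ...)
  graphics::abline(0, 1, lty = 3)
  if (x$predictor_kind == "ordinal") {
    graphics::points(x$points$fpr, x$points$tpr, pch = 19)
  }
  invisible(x)
}

#' DeLong's test for two correlated ROC curves
#'
#' Paired comparison of the AUROCs of two predictors evaluated on the same
#' records, using the structural-components covariance of the DeLong
#' placements; the null hypothesis is no difference in AUROC.
#'
#' @param pred_a,pred_b Two numeric predictors on the same records.
#' @param obs Binary outcomes.
#' @return List of class `delong_result`: `auroc_a`, `auroc_b`, `variance`
#'   (of the difference), `z`, `p` (two-sided).
#' @export
delong_compare <- function(pred_a, pred_b, obs) {
  obs <- .check_binary(obs)
  stopifnot(length(pred_a) == length(obs), length(pred_b) == length(obs))
  pa <- .delong_placements(pred_a, obs)
  pb <- .delong_placements(pred_b, obs)
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (v < 0 && v > -1e-15) v <- 0
  d <- pa$auc - pb$auc
  z <- if (v == 0) 0 else d / sqrt(v)
  structure(list(auroc_a = pa$auc, auroc_b = pb$auc, variance = v, z = z,
                 p = if (v == 0 && d == 0) 1 else 2 * stats::pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong test: AUROC %.3f vs %.3f, z = %.3f, p = %.3g\n",
              x$auroc_a, x$auroc_b, x$z, x$p))
  invisible(x)
}

#' Continuous net reclassification improvement
#'
#' For events, the net proportion whose predicted risk rises under the new
#' model; for non-events, the net proportion whose risk falls; the total
#' NRI is their sum (range [-2, 2]). Exact ties count in neither
#' direction. The standard error uses the standard asymptotic formula and
#' the z-test is two-sided.
#'
#' @param pred_old,pred_new Risk predictions under the reference and the
#'   new model.
#' @param obs Binary outcomes.
#' @return List of class `nri_result`: `nri_events`, `nri_nonevents`,
#'   `nri_total`, `se`, `z`, `p`.
#' @export
continuous_nri <- function(pred_old, pred_new, obs) {
  obs <- .check_binary(obs)
  stopifnot(length(pred_old) == length(obs),
            length(pred_new) == length(obs))
  up <- pred_new > pred_old
  dn <- pred_new < pred_old
  e <- obs == 1L
  n_e <- sum(e); n_ne <- sum(!e)
  p_up_e <- mean(up[e]);  p_dn_e <- mean(dn[e])
  p_up_ne <- mean(up[!e]); p_dn_ne <- mean(dn[!e])
  nri_e <- p_up_e - p_dn_e
  nri_ne <- p_dn_ne - p_up_ne
  se <- sqrt((p_up_e + p_dn_e - (p_up_e - p_dn_e)^2) / n_e +
             (p_up_ne + p_dn_ne - (p_dn_ne - p_up_ne)^2) / n_ne)
  total <- nri_e + nri_ne
  z <- if (se == 0) 0 else total / se
  structure(list(nri_events = nri_e, nri_nonevents = nri_ne,
                 nri_total = total, se = se, z = z,
                 ci95 = c(lower = total - 1.96 * se,
                          upper = total + 1.96 * se),
                 p = if (se == 0 && total == 0) 1 else
                   2 * stats::pnorm(-abs(z))),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "Continuous NRI = %.3f (events %.3f + nonevents %.3f), 95%% CI %.3f-%.3f, p = %.3g\n",
    x$nri_total, x$nri_events, x$nri_nonevents, x$ci95["lower"],
    x$ci95["upper"], x$p))
  invisible(x)
}

#' Net benefit at a risk threshold
#'
#' Net benefit of labelling patients with predicted risk at or above
#' threshold `t` as high-risk: `TP/n - (FP/n) * t/(1-t)` — the true-positive
#' proportion minus the false-positive proportion weighted by the odds of
#' the threshold.
#'
#' @param pred Predicted probabilities.
#' @param obs Binary outcomes.
#' @param threshold Risk threshold strictly inside (0, 1).
#' @return Net benefit (scalar).
#' @export
net_benefit <- function(pred, obs, threshold) {
  stopifnot(length(pred) == length(obs))
  if (!is.numeric(threshold) || any(threshold <= 0 | threshold >= 1)) {
    stop("`threshold` must lie strictly inside (0, 1)")
  }
  obs <- as.integer(obs)
  n <- length(obs)
  vapply(threshold, function(t) {
    hi <- pred >= t
    (sum(hi & obs == 1L) - sum(hi & obs == 0L) * t / (1 - t)) / n
  }, 0)
}

#' Decision-curve analysis
#'
#' Evaluates net benefit over a grid of high-risk thresholds for a model,
#' alongside the treat-all policy (everyone high-risk) and treat-none
#' (identically zero). The default grid spans 0.1%--50% in 0.1% steps.
#'
#' @param pred Predicted probabilities.
#' @param obs Binary outcomes.
#' @param grid Threshold grid inside (0, 1).
#' @return Object of class `decision_curve`: data frame `curve` with
#'   columns `threshold`, `nb_model`, `nb_all`, `nb_none`, plus
#'   `prevalence`.
#' @export
decision_curve <- function(pred, obs, grid = seq(0.001, 0.5, by = 0.001)) {
  obs <- .check_binary(obs)
  prev <- mean(obs)
  nb <- net_benefit(pred, obs, grid)
  nb_all <- prev - (1 - prev) * grid / (1 - grid)
  structure(list(curve = data.frame(threshold = grid, nb_model = nb,
                                    nb_all = nb_all, nb_none = 0),
                 prevalence = prev),
            class = "decision_curve")
}

#' @export
plot.decision_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$threshold, cv$nb_model, type = "l", lwd = 2,
                 ylim = range(c(cv$nb_model, 0, x$prevalence)),
                 xlab = "High-risk threshold", ylab = "Net benefit", ...)
  graphics::lines(cv$threshold, cv$nb_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("model", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1), bty = "n")
  invisible(x)
}

#' Bootstrap optimism correction
#'
#' Internal validation by the bootstrap: for each of `B` replicates the
#' cohort is resampled with replacement, the model refitted on the
#' resample, and the metric evaluated both on the resample (apparent) and
#' on the original cohort (test); optimism is the mean apparent-minus-test
#' difference and the corrected metric is apparent performance minus
#' optimism. Replicates whose refit fails (e.g. an empty category in a
#' small resample) are dropped and counted; more than 10% failures is an
#' error.
#'
#' @param data Cohort data frame.
#' @param fit_fun Function `data -> model` (deterministic given data).
#' @param metric_fun Function `(model, data) -> scalar metric`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed controlling the resampling.
#' @return Object of class `optimism_report`: `metric` name, `apparent`,
#'   `optimism`, `corrected` (= apparent - optimism), `B`, `B_failed`,
#'   `seed`, and the per-replicate `optimism_values`.
#' @param metric_name Label stored in the report.
#' @export
bootstrap_optimism <- function(data, fit_fun, metric_fun, B = 1000,
                               seed = 1L, metric_name = "metric") {
  stopifnot(is.data.frame(data), B >= 1)
  apparent <- metric_fun(fit_fun(data), data)
  set.seed(seed)
  n <- nrow(data)
  opt <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    boot <- data[idx, , drop = FALSE]
    res <- tryCatch({
      m <- fit_fun(boot)
      metric_fun(m, boot) - metric_fun(m, data)
    }, error = function(e) NA_real_)
    opt[b] <- res
  }
  failed <- sum(is.na(opt))
  if (failed > 0.1 * B) {
    stop(failed, " of ", B, " bootstrap replicates failed to refit")
  }
  optimism <- mean(opt, na.rm = TRUE)
  structure(list(metric = metric_name, apparent = apparent,
                 optimism = optimism, corrected = apparent - optimism,
                 B = B, B_failed = failed, seed = seed,
                 optimism_values = opt),
            class = "optimism_report")
}

#' @export
print.optimism_report <- function(x, ...) {
  cat(sprintf(
    "Optimism-corrected %s: apparent %.4f - optimism %.4f = %.4f (B = %d%s)\n",
    x$metric, x$apparent, x$optimism, x$corrected, x$B,
    if (x$B_failed) sprintf(", %d failed", x$B_failed) else ""))
  if (x$B < 30) cat("NOTE: B < 30 replicates; low-precision optimism estimate\n")
  invisible(x)
}
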