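# The combined subjective + SORT logistic model.
#
# ln(R / (1 - R)) = b0 + b1(category) + b2 * sort_pct
#
# where R is the probability of 30-day inpatient death, `category` is the
# clinician's 6-level subjective risk interval entering as dummies with
# "<1%" as reference (so b1(1) = 0), and sort_pct is the SORT-predicted
# mortality risk in percent (per 1% risk). The model can be used with its
# published coefficients or refitted by maximum likelihood on a cohort.

#' Published coefficients of the combined model
#'
#' The reference coefficient surface of the combined subjective + SORT
#' logistic model: intercept -6.403; SORT-predicted risk (per 1% risk)
#' 0.04028; subjective-category coefficients relative to the "<1%" reference
#' of 1.487, 2.365, 3.074, 4.156 and 5.028 for categories 2--6, with their
#' standard errors.
#'
#' @return An object of class `combined_coefs`: list with `b0` (intercept),
#'   `b2` (slope per 1% SORT risk), `b1` (length-6 vector of category
#'   effects, first element 0), `se` (named standard errors), and
#'   `provenance`.
#' @export
published_combined_coefs <- function() {
  structure(list(
    b0 = -6.403,
    b2 = 0.04028,
    b1 = c(0, 1.487, 2.365, 3.074, 4.156, 5.028),
    se = c(intercept = 0.2135, sort_pct = 0.007049, cat2 = 0.2962,
           cat3 = 0.3177, cat4 = 0.2976, cat5 = 0.2852, cat6 = 0.3186),
    provenance = "published"),
    class = "combined_coefs")
}

.as_combined_coefs <- function(x) {
  if (inherits(x, "combined_coefs")) return(x)
  if (inherits(x, "combined_model")) return(x$coefs)
  stop("expected a combined_coefs or combined_model object")
}

#' @export
print.combined_coefs <- function(x, ...) {
  cat("<combined_coefs>", x$provenance, "\n")
  cat(sprintf("  intercept %.4f; SORT slope (per 1%% risk) %.5f\n",
              x$b0, x$b2))
  cat("  category effects (ref <1%):",
      paste(sprintf("%.3f", x$b1[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' Predict 30-day mortality from the combined model
#'
#' Evaluates expit(b0 + b1(category) + b2 * sort_pct). Category 1 ("<1%")
#' is the reference and contributes 0. The SORT prediction enters in
#' percent units (per 1% risk), not as a proportion.
#'
#' @param category Integer vector of subjective categories in 1..6.
#' @param sort_pct Numeric vector of SORT-predicted risks in percent
#'   (non-negative).
#' @param coefs A `combined_coefs` object (default the published set) or a
#'   fitted `combined_model`.
#' @return Numeric vector of predicted probabilities of 30-day death.
#' @export
predict_combined <- function(category, sort_pct,
                             coefs = published_combined_coefs()) {
  coefs <- .as_combined_coefs(coefs)
  category <- as.integer(category)
  if (any(is.na(category)) || any(category < 1L | category > 6L)) {
    stop("`category` must be in 1..6 with no missing values")
  }
  if (any(is.na(sort_pct)) || any(sort_pct < 0)) {
    stop("`sort_pct` must be non-negative SORT-predicted risk in percent")
  }
  stats::plogis(coefs$b0 + coefs$b1[category] + coefs$b2 * sort_pct)
}

#' Predicted-risk surface of the combined model
#'
#' Evaluates the combined model over a grid of SORT-predicted risks for all
#' six subjective categories — the conditional-probability fan showing how
#' the two information sources combine.
#'
#' @param coefs `combined_coefs` or fitted `combined_model`.
#' @param sort_grid Numeric grid of SORT-predicted risks in percent.
#' @return Data frame with columns `category`, `sort_pct`, `risk`.
#' @export
combined_surface <- function(coefs = published_combined_coefs(),
                             sort_grid = seq(0, 50, by = 0.5)) {
  grid <- expand.grid(category = 1:6, sort_pct = sort_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$risk <- predict_combined(grid$category, grid$sort_pct, coefs)
  grid[order(grid$category, grid$sort_pct), , drop = FALSE]
}

#' Fit the combined subjective + SORT logistic model
#'
#' Unpenalized maximum-likelihood fit of
#' `death ~ factor(category) + sort_pct` with the "<1%" category as
#' reference. The cohort should already be restricted to records with a
#' subjective category present and assessed by clinical judgement and/or
#' ASA-PS alone. Complete separation and empty categories raise errors
#' (naming the category) rather than silently regularizing, because the
#' published coefficients are the reference surface.
#'
#' @param data Data frame containing the model columns.
#' @param category_col,sort_col,outcome_col Column names of the subjective
#'   category (1..6), SORT-predicted risk in percent, and binary 30-day
#'   death outcome.
#' @return An object of class `combined_model` with components `coefs`
#'   (a `combined_coefs` with `provenance = "fitted"`), `vcov`, `fit` (the
#'   underlying `glm`), `n`, `events` and `call`. Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `predict()`, `simulate()`,
#'   `residuals()` and `plot()`.
#' @export
fit_combined <- function(data, category_col = "subjective_category",
                         sort_col = "sort_risk_pct",
                         outcome_col = "death30_inpatient") {
  stopifnot(is.data.frame(data))
  for (v in c(category_col, sort_col, outcome_col)) {
    if (!v %in% names(data)) stop("column not found: ", v)
  }
  cat_ <- as.integer(data[[category_col]])
  sortp <- as.numeric(data[[sort_col]])
  y <- as.integer(data[[outcome_col]])
  if (anyNA(cat_) || any(cat_ < 1L | cat_ > 6L)) {
    stop("subjective category must be present and in 1..6 for every record ",
         "(restrict to the subjective-assessment subcohort first)")
  }
  if (anyNA(sortp) || any(sortp < 0)) stop("invalid SORT risk column")
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("outcome must be binary 0/1")
  present <- sort(unique(cat_))
  empty <- setdiff(1:6, present)
  if (length(empty)) {
    stop("empty subjective categor", if (length(empty) > 1) "ies: " else "y: ",
         paste(empty, collapse = ", "),
         " (cannot estimate its coefficient)")
  }
  df <- data.frame(y = y, cat = factor(cat_, levels = 1:6), sort_pct = sortp)
  # separation is detected explicitly below, so IRLS warnings about fitted
  # probabilities of 0/1 are redundant noise
  fit <- suppressWarnings(
    stats::glm(y ~ cat + sort_pct, family = stats::binomial(), data = df))
  if (!fit$converged) {
    stop("combined-model fit did not converge after ", fit$iter,
         " IRLS iterations")
  }
  cf <- stats::coef(fit)
  if (anyNA(cf) || any(abs(cf) > 30) ||
      any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)) {
    stop("apparent complete separation: coefficient(s) diverged (",
         paste(names(cf)[is.na(cf) | abs(cf) > 30], collapse = ", "), ")")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  coefs <- structure(list(
    b0 = unname(cf["(Intercept)"]),
    b2 = unname(cf["sort_pct"]),
    b1 = c(0, unname(cf[paste0("cat", 2:6)])),
    se = c(intercept = unname(se["(Intercept)"]),
           sort_pct = unname(se["sort_pct"]),
           structure(unname(se[paste0("cat", 2:6)]),
                     names = paste0("cat", 2:6))),
    provenance = "fitted"), class = "combined_coefs")
  structure(list(coefs = coefs, vcov = stats::vcov(fit), fit = fit,
                 n = length(y), events = sum(y),
                 data = df, call = match.call()),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat("Combined subjective + SORT logistic model\n")
  cat(sprintf("  n = %d episodes, %d deaths (%.2f%%)\n", x$n, x$events,
              100 * x$events / x$n))
  print(x$coefs)
  invisible(x)
}

#' @export
coef.combined_model <- function(object, ...) {
  c(intercept = object$coefs$b0,
    structure(object$coefs$b1[-1], names = paste0("cat", 2:6)),
    sort_pct = object$coefs$b2)
}

#' @export
vcov.combined_model <- function(object, ...) object$vcov

#' @export
summary.combined_model <- function(object, ...) {
  cf <- coef(object)
  se <- object$coefs$se[c("intercept", paste0("cat", 2:6), "sort_pct")]
  z <- cf / se
  tab <- data.frame(coefficient = cf, std_error = unname(se), z = z,
                    p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(table = tab, n = object$n, events = object$events,
                 deviance = object$fit$deviance,
                 null_deviance = object$fit$null.deviance,
                 aic = stats::AIC(object$fit)),
            class = "summary.combined_model")
}

#' @export
print.summary.combined_model <- function(x, ...) {
  cat("Combined subjective + SORT logistic model\n")
  cat(sprintf("  n = %d, events = %d; deviance %.1f (null %.1f), AIC %.1f\n",
              x$n, x$events, x$deviance, x$null_deviance, x$aic))
  print(round(x$table, 5))
  invisible(x)
}

#' @export
predict.combined_model <- function(object, newdata = NULL,
                                   category_col = "subjective_category",
                                   sort_col = "sort_risk_pct", ...) {
  if (is.null(newdata)) {
    return(unname(stats::fitted(object$fit)))
  }
  predict_combined(newdata[[category_col]], newdata[[sort_col]],
                   object$coefs)
}

#' @export
simulate.combined_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::fitted(object$fit)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
residuals.combined_model <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit, type = type)
}

#' Plot the combined model's predicted-risk fan
#'
#' Draws predicted 30-day mortality against SORT-predicted risk, one curve
#' per subjective category (base graphics).
#'
#' @param x A `combined_model` or `combined_coefs`.
#' @param sort_grid Grid of SORT-predicted risks in percent.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.combined_model <- function(x, sort_grid = seq(0, 50, by = 0.5), ...) {
  surf <- combined_surface(x$coefs, sort_grid)
  m <- matrix(surf$risk[order(surf$sort_pct, surf$category)],
              ncol = 6, byrow = TRUE)
  graphics::matplot(sort_grid, m, type = "l", lty = 1, lwd = 2,
                    xlab = "SORT-predicted risk (%)",
                    ylab = "Combined-model predicted risk",
                    main = "Combined subjective + SORT model", ...)
  graphics::legend("topleft", legend = subjective_scale()$label,
                   col = 1:6, lty = 1, lwd = 2, bty = "n",
                   title = "Subjective category")
  invisible(surf)
}
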