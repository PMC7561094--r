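test_that("auroc handles the canonical endpoint cases", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auroc, 1)
  expect_equal(auroc(rep(0.3, 10), rep(0:1, 5))$auroc, 0.5)  # ties 1/2
  expect_equal(auroc(c(0.1, 0.4, 0.2), c(0, 0, 1))$auroc, 0.5)
  expect_error(auroc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("auroc is invariant under strictly monotone transforms", {
  set.seed(7)
  pred <- runif(300)
  obs <- rbinom(300, 1, plogis(3 * pred - 2))
  a0 <- auroc(pred, obs)$auroc
  for (f in list(function(x) 10 * x - 2, function(x) x^3,
                 function(x) plogis(5 * x), exp)) {
    expect_equal(auroc(f(pred), obs)$auroc, a0, tolerance = 1e-12)
  }
})

test_that("ROC operating points integrate to the Mann-Whitney area", {
  set.seed(11)
  pred <- round(runif(500), 2)
  obs <- rbinom(500, 1, 0.2 + 0.5 * pred)
  r <- auroc(pred, obs)
  pts <- r$points
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, r$auroc, tolerance = 1e-12)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(!is.unsorted(pts$fpr))
})

test_that("auroc agrees with pROC including the DeLong interval", {
  skip_if_not_installed("pROC")
  set.seed(19)
  pred <- runif(400)
  obs <- rbinom(400, 1, plogis(4 * pred - 3))
  r <- auroc(pred, obs)
  pr <- pROC::roc(obs, pred, quiet = TRUE, direction = "<")
  expect_equal(r$auroc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(unname(r$ci95), ci[c(1, 3)], tolerance = 1e-9)
})

test_that("the ordinal polygon ROC has one point per category and its
           trapezoid equals the rank statistic", {
  # hand-built 12-record table over 6 categories
  cats <- c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 6, 6)
  obs  <- c(0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 0, 1)
  r <- auroc_ordinal(cats, obs)
  expect_identical(r$predictor_kind, "ordinal")
  expect_equal(nrow(r$points), 7)  # 6 thresholds + origin
  # hand-computed trapezoid: cases at cats (4,5,6), controls elsewhere
  expect_equal(r$auroc, brute_force_auc(cats, obs), tolerance = 1e-12)

  expect_equal(auroc_ordinal(c(1, 1, 2, 2), c(0, 0, 1, 1))$auroc, 1)
  expect_error(auroc_ordinal(rep(2, 6), rep(0:1, 3)), "distinct")
})

test_that("categories independent of outcome give chance-level polygon
           area", {
  set.seed(5)
  n <- 30000
  cats <- sample(1:6, n, replace = TRUE)
  obs <- rbinom(n, 1, 0.05)
  r <- auroc_ordinal(cats, obs)
  expect_lt(abs(r$auroc - 0.5), 3 * sqrt(r$variance))
})

test_that("delong comparison identities hold", {
  set.seed(3)
  pred <- runif(200)
  obs <- rbinom(200, 1, plogis(2 * pred - 2))
  d_self <- delong_compare(pred, pred, obs)
  expect_equal(d_self$z, 0)
  expect_equal(d_self$p, 1)
  d_mono <- delong_compare(pred, plogis(7 * pred - 1), obs)
  expect_equal(d_mono$z, 0)
  # swapping the predictors negates z exactly
  a <- runif(200); b <- runif(200)
  dz1 <- delong_compare(a, b, obs)
  dz2 <- delong_compare(b, a, obs)
  expect_equal(dz1$z, -dz2$z, tolerance = 1e-12)
  expect_equal(dz1$p, dz2$p, tolerance = 1e-12)
  expect_gte(dz1$variance, 0)
})

test_that("continuous NRI components match hand counts and identities", {
  p <- runif(50); y <- rep(0:1, 25)
  self <- continuous_nri(p, p, y)
  expect_equal(self$nri_total, 0)
  expect_equal(self$p, 1)

  # maximum attainable: both events up, both nonevents down
  old <- c(0.2, 0.2, 0.5, 0.5)
  new <- c(0.4, 0.3, 0.1, 0.2)
  y4 <- c(1, 1, 0, 0)
  expect_equal(continuous_nri(old, new, y4)$nri_total, 2)

  # toy set with hand-listed movements: 4 events (3 up, 1 down),
  # 6 nonevents (2 up, 3 down, 1 tied)
  old10 <- c(0.10, 0.20, 0.30, 0.40, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60)
  new10 <- c(0.20, 0.30, 0.40, 0.30, 0.20, 0.30, 0.20, 0.30, 0.40, 0.60)
  y10 <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  r <- continuous_nri(old10, new10, y10)
  expect_equal(r$nri_events, (3 - 1) / 4)
  expect_equal(r$nri_nonevents, (3 - 2) / 6)
  expect_equal(r$nri_total, 0.5 + 1 / 6)

  # antisymmetry
  set.seed(2)
  a <- runif(100); b <- runif(100); yy <- rbinom(100, 1, 0.4)
  if (length(unique(yy)) < 2) yy[1:2] <- 0:1
  r_ab <- continuous_nri(a, b, yy)
  r_ba <- continuous_nri(b, a, yy)
  expect_equal(r_ab$nri_total, -r_ba$nri_total, tolerance = 1e-12)
  expect_equal(r_ab$se, r_ba$se, tolerance = 1e-12)
})

test_that("net benefit matches hand arithmetic and decision-curve
           identities hold", {
  # n = 100, 10 events; 8 true positives, 20 false positives at t = 0.2
  pred <- c(rep(0.9, 8), rep(0.05, 2), rep(0.9, 20), rep(0.05, 70))
  obs <- c(rep(1, 10), rep(0, 90))
  expect_equal(net_benefit(pred, obs, 0.2), 0.08 - 0.20 * 0.25)

  expect_equal(net_benefit(rep(0.01, 50), rep(0:1, 25), 0.5), 0)
  expect_error(net_benefit(pred, obs, 1.5), "strictly inside")

  set.seed(4)
  y <- rbinom(400, 1, 0.3)
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  prev <- mean(y)
  dc <- decision_curve(runif(400), y)
  expect_true(all(dc$curve$nb_none == 0))
  # treat-all crosses zero exactly at the prevalence
  expect_equal(prev - (1 - prev) * prev / (1 - prev), 0)
  above <- dc$curve$threshold < prev
  expect_true(all(dc$curve$nb_all[above] > 0))
  expect_true(all(dc$curve$nb_all[!above & dc$curve$threshold > prev] < 0))
  # a perfect predictor attains the prevalence at every threshold
  dc_perf <- decision_curve(y, y, grid = c(0.05, 0.3, 0.8))
  expect_equal(dc_perf$curve$nb_model, rep(prev, 3))
})

test_that("calibration bins conserve counts and match a hand-binned toy
           table", {
  pred <- rep(c(0.1, 0.2, 0.3, 0.4), each = 5)
  obs <- c(1, 0, 0, 0, 0,  0, 1, 0, 0, 0,  1, 1, 0, 0, 0,  1, 1, 1, 0, 0)
  cal <- calibration(pred, obs, n_bins = 4)
  expect_equal(cal$bins$n, rep(5, 4))
  expect_equal(cal$bins$deaths, c(1, 1, 2, 3))
  expect_equal(cal$bins$mean_pred, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(cal$bins$obs_prop, c(0.2, 0.2, 0.4, 0.6))
  expect_equal(sum(cal$bins$deaths), sum(obs))
  expect_equal(sum(cal$bins$n), length(obs))
})

test_that("perfectly calibrated group rates give a zero HL statistic", {
  rates <- seq(0.05, 0.5, by = 0.05)
  n_per <- 20
  pred <- rep(rates, each = n_per)
  obs <- unlist(lapply(rates, function(r) {
    k <- round(r * n_per)
    c(rep(1, k), rep(0, n_per - k))
  }))
  pred_exact <- rep(vapply(rates, function(r) round(r * n_per) / n_per, 0),
                    each = n_per)
  cal <- calibration(pred_exact, obs, n_bins = 10)
  expect_equal(cal$HL_statistic, 0, tolerance = 1e-12)
  expect_equal(cal$HL_df, 8)
  expect_equal(cal$HL_p, 1)
})

test_that("a constant predictor degenerates to a flagged single bin", {
  cal <- calibration(rep(0.3, 50), rep(0:1, 25))
  expect_true(cal$degenerate)
  expect_equal(nrow(cal$bins), 1)
  expect_true(is.na(cal$HL_statistic))
})

test_that("optimism of a constant metric is exactly zero", {
  df <- data.frame(x = 1:20)
  rep_ <- bootstrap_optimism(df, function(d) NULL,
                             function(m, d) 0.75, B = 10, seed = 1)
  expect_equal(rep_$optimism, 0)
  expect_equal(rep_$corrected, rep_$apparent)
  expect_equal(rep_$corrected, 0.75)
})

test_that("bootstrap resampling is deterministic given the seed and counts
           failed replicates", {
  df <- data.frame(y = rbinom(100, 1, 0.4), x = rnorm(100))
  fit <- function(d) glm(y ~ x, family = binomial(), data = d)
  metric <- function(m, d) auroc(predict(m, d, type = "response"), d$y)$auroc
  r1 <- bootstrap_optimism(df, fit, metric, B = 30, seed = 99)
  r2 <- bootstrap_optimism(df, fit, metric, B = 30, seed = 99)
  expect_identical(r1$optimism_values, r2$optimism_values)
  fragile <- function(d) if (runif(1) < 0.5) stop("boom") else fit(d)
  expect_error(
    bootstrap_optimism(df, fragile, metric, B = 30, seed = 1),
    "replicates failed")
})
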