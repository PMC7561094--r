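---
title: "Perioperative mortality risk models and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perioperative mortality risk models and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surgrisk)
```

## The problem

Before inpatient surgery, the perioperative team is asked to estimate the
patient's risk of death within 30 days. In routine practice this estimate is
usually *subjective* — clinical judgement, sometimes anchored on the ASA-PS
fitness grade — expressed on a 6-interval ordinal scale (<1%, 1%–2.5%,
2.6%–5%, 5.1%–10%, 10.1%–50%, >50%). Several *objective* logistic risk
models exist (SORT, P-POSSUM, SRS) that map routinely collected covariates
to a mortality probability. `surgrisk` implements both kinds of predictor,
a combined subjective-plus-SORT logistic model, and the full battery of
statistics used to validate and compare prognostic models on a binary
outcome: calibration with the Hosmer–Lemeshow test, ROC/AUROC (including
the ordinal "polygon" ROC for categorical predictors), DeLong's test for
two correlated ROC curves, the continuous net reclassification improvement
(NRI), decision-curve analysis, and bootstrap optimism correction for
internal validation.

## The models

**Objective engines.** Each objective model is a logit-link scoring
specification: risk $= \operatorname{expit}(\beta_0 + \sum_j \beta_j x_j)$,
where the $x_j$ are category dummies or integer sub-scores derived from the
patient record. The three shipped specifications are versioned JSON configs
with provenance strings:

* **SORT** — six variable groups: ASA-PS (III/IV/V vs I–II), NCEPOD
  urgency, a high-risk-specialty flag (gastrointestinal, thoracic/cardiac,
  vascular), procedure severity (Xmajor/complex), active malignancy, and
  age band (65–79, 80+).
* **P-POSSUM** — $\text{logit}(R) = -9.065 + 0.1692\,PS + 0.1550\,OS$,
  where $PS$ is the 12-item physiological sub-score and $OS$ the 6-item
  operative-severity sub-score, every item scored 1/2/4/8. The banding
  tables live in the JSON config, not in code, so band edits never require
  a code change.
* **SRS** — $\text{logit}(R) = -9.81 + 0.84\,(\text{CEPOD} + \text{BUPA} +
  \text{ASA})$, a points sum of urgency class, severity grade and ASA-PS.

The engine itself is model-agnostic: `score_model()` resolves each term
through the spec's `variable_map` into features derived from the canonical
record. The coefficients were transcribed from the original model
publications; the provenance string of each config records this, and the
configs should be re-verified against those sources before any clinical
use. Models predating the NCEPOD "expedited" category need a documented
mapping for it: the P-POSSUM config maps expedited to the elective
operative-mode band and the SRS config to the historical "scheduled" class
(2); both are config entries, overridable without touching code.

**Missing physiology.** Fit patients often reach theatre without
preoperative bloods, so missing physiology is imputed at *normal values*
(sodium 140 mmol/L, potassium 4.0 mmol/L, urea 5.0 mmol/L, haemoglobin
14.0 g/dL, WBC 8.0×10⁹/L, pulse 75 bpm, systolic BP 120 mmHg, GCS 15, ECG
normal) before scoring — each default sits in the minimum-score POSSUM
band, so imputation can never inflate a sub-score. Per-field flags are
returned for audit, and a complete-case rule is applied afterwards to the
non-lab analysis variables.

**The combined model.** The package's core is the two-variable logistic
model

$$\ln\frac{R}{1-R} = \beta_0 + \beta_1(\text{category}) +
\beta_2 \cdot \text{SORT}\%$$

with the subjective category entering as dummies (reference "<1%") and the
SORT prediction entering **in percent** (per 1% of predicted risk).
Percent-vs-proportion is the likeliest unit bug in reimplementations, so it
is pinned by unit tests at the published coefficients. `fit_combined()` is
unpenalized maximum likelihood via `glm()`; complete separation and empty
categories raise errors rather than silently regularizing, because the
published coefficient set is the reference surface. The fitted object
supports `print`, `summary`, `coef`, `vcov`, `predict`, `simulate`,
`residuals` and `plot` (the monotone fan of predicted-risk curves over a
SORT grid).

**Midpoints.** When an interval-valued subjective category must enter an
analysis on the probability scale (calibration, NRI, decision curves), it
is represented by its interval midpoint: 0.5%, 1.75%, 3.8%, 7.55%, 30.05%,
and a configurable midpoint for the open-ended ">50%" category defaulting
to 75% (the arithmetic midpoint of 50–100%). The top midpoint is used only
for calibration/NRI/DCA of the subjective predictor — never inside the
combined model, which uses dummies. The ROC of the subjective predictor
uses the raw categories (polygon), which is invariant to the midpoint
choice.

## Validation statistics: conventions that matter

* **AUROC** is the Mann–Whitney concordance with ties counted ½; the code
  asserts internally that it equals the trapezoidal area under the
  empirical ROC points to 1e-12. Variance and CIs use DeLong's placement
  estimator.
* **Ordinal ROC**: one operating point per category threshold; the area of
  the resulting polygon equals the ties-½ rank statistic on category
  ranks.
* **DeLong's test** uses the structural-components covariance; swapping
  the two predictors negates $z$ exactly, and a self-comparison returns
  $z = 0$, $p = 1$.
* **Continuous NRI**: events moving up and non-events moving down count as
  improvement; exact ties count in neither direction (the alternative —
  splitting ties — changes small-sample values, so the choice is pinned
  here). SE by the standard asymptotic formula.
* **Hosmer–Lemeshow**: deciles of predicted risk with ties kept together
  (merged quantile breaks), statistic
  $\sum_g (O_g-E_g)^2/(E_g(1-E_g/n_g))$, df = bins − 2. The df is a report
  field so a reader can re-derive the p-value under the df = bins
  convention. A constant predictor yields a flagged single-bin result with
  the test undefined rather than an error.
* **Decision curves**: net benefit $TP/n - (FP/n)\,t/(1-t)$ with high-risk
  defined as predicted risk ≥ t; grid default 0.1%–50% in 0.1% steps.
  Treat-none is identically zero and treat-all crosses zero at the
  prevalence — both identities are tested.
* **Optimism correction**: resample episodes with replacement (no cluster
  bootstrap), refit, evaluate on resample and on the original cohort;
  corrected = apparent − mean optimism. Failed replicate refits are
  dropped and counted, with >10% failures an error.
* **Calibration bin CIs** are Wilson intervals; the smoothed
  observed-vs-predicted curve is `lowess` with span 2/3 — a fixed,
  documented bandwidth choice.

## The synthetic cohort generator

Real patient-level data of this kind cannot be redistributed, so every
downstream stage is exercised on synthetic cohorts from
`generate_cohort()`. The generator emulates the cohort structure the
analysis assumes:

* **Marginals**: covariate frequencies default to the published cohort mix
  (53.3% elective; ASA I–V 19.7/45.0/29.0/5.9/0.3%; severity, specialty,
  malignancy, comorbidity and country mixes likewise). Age is a truncated
  normal centred at 62 with SD 19 (median ≈ 62, IQR ≈ 46–73). Labs are
  drawn near their normal ranges.
* **True risk** is generated from a configurable `risk_model_spec` —
  default SORT, so cohorts are SORT-calibrated by construction — with the
  intercept shifted by bisection so the expected cohort mortality equals
  `mortality_target` (default 1.4%). Setting `mortality_target = NULL`
  skips the tuning and leaves the DGM exactly as specified.
* **Clinician behaviour** is modelled on the logit scale: the assigned
  category bins $\operatorname{expit}(\text{bias} + \text{slope}\cdot
  \text{logit}(p) + \varepsilon)$, $\varepsilon \sim N(0,
  \text{noise}^2)$. The defaults (slope 1, bias +0.7 logits, noise SD 1.0
  logit) make simulated clinicians overpredict mortality in every category
  while discriminating well — the qualitative behaviour observed in
  practice.
* **Missingness** applies to the blood panel as a block, with probability
  decreasing in ASA-PS (35%, 20%, 8%, 3%, 1% for ASA I–V): fit patients
  are the ones without preoperative bloods. This averages to roughly 19%
  of episodes with an incomplete P-POSSUM panel.
* **Assessment methods**: 21.1% of episodes are flagged as aided by an
  objective tool (subdivided to mirror published usage rates), 88.7% carry
  the clinical-judgement flag and 38.1% the ASA-PS flag.
* **Dependence**: only marginal distributions are published, so any joint
  structure is a modelling choice. The package applies a Gaussian copula
  with age–ASA rank correlation 0.5 and urgency–severity correlation 0.35
  by default. Fully independent covariates dilute the risk concentration
  that real cohorts exhibit — under independence the SORT's AUROC on its
  own cohorts falls to ≈0.85 rather than the ≈0.88–0.90 regime the
  generator is meant to emulate — and older/sicker and
  urgent/major-surgery associations are clinically uncontroversial. Pass
  `dependence = NULL` for independent draws.

What passing tests on these cohorts do **not** show: the generator draws
most covariates independently, has no hospital-level clustering or country
effect, no calibration drift, and clinician behaviour is a two-parameter
logit mechanism. Agreement of the statistics on synthetic cohorts
demonstrates correctness of the *procedures*, not the real-world
performance of any model.

## The study pipeline

`run_study()` reproduces a three-part analysis flow from one raw cohort
table: (1) exclusions in a fixed, logged order — eligibility flags
(obstetric, under-18, ambulatory), then complete-case on the non-lab
analysis variables, then carve-out of tool-assisted episodes (the order
changes the counts, so it is frozen and every count is logged); (2)
external validation of SORT/P-POSSUM/SRS on the validation cohort
(calibration + HL, AUROC, pairwise DeLong); (3) on the subjective-only
subcohort, midpoint calibration and polygon ROC of subjective assessment,
SORT-vs-subjective DeLong and NRI, the combined-model fit with
bootstrap-optimism-corrected AUROC (B = 1000 by default), a comparison
table, decision curves for all predictors, and the predicted-risk surface
over a SORT grid (0–50% in 0.5% steps by default). `run_subgroup()` reruns
the pipeline on a predicate-selected subset, refusing subgroups with fewer
than 20 events by default.

## Numerical and design choices

* Degenerate inputs: single-class outcomes are errors for ROC-based
  statistics; constant predictors are valid for calibration (flagged
  single bin) and for AUROC (0.5 by the ties convention).
* POSSUM band lookup is first-match over ordered bands; published bands
  have small typographical gaps (e.g. haemoglobin 12.9 vs 13.0), and a
  value falling in a gap takes the nearest band's score.
* `true_risk` is retained as a column of generated cohorts. It is the
  generator's ground truth for testing (e.g. Hosmer–Lemeshow null
  behaviour) and is ignored by the pipeline.
* All randomness flows from explicit integer seeds; a fixed config seed
  makes `generate_cohort()` bit-identical across runs, and
  `bootstrap_optimism()` is deterministic given its seed.
* Problem sizes in the shipped tests were chosen to make sampling error
  negligible relative to the asserted bounds while keeping the default
  suite quick: marginal checks at n = 50,000, mortality targeting at
  n = 100,000, coefficient recovery at n = 200,000, bootstrap suites at
  B = 200, and the DeLong permutation cross-check at n = 500 with 20,000
  permutations.

## Known limitations

* The shipped SORT/P-POSSUM/SRS coefficient configs are transcriptions;
  they reproduce the published equation structures and plausible risk
  distributions, but transcription fidelity should be re-verified against
  the original publications before any use beyond simulation.
* The ">50%" midpoint (75%) is a convention; no published value exists for
  the open-ended interval. It affects only midpoint-based statistics of
  the subjective predictor.
* The combined model assumes the subjective category is present for every
  record (complete-case); records missing it are excluded by the pipeline
  rather than imputed.
* Hosmer–Lemeshow p-values on very large cohorts detect trivially small
  miscalibration; the calibration bins and smoothed curve are the primary
  evidence, the test a convention.
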