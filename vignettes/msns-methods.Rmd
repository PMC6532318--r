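---
title: "Scoring, validation statistics, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, validation statistics, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msns)
```

## The score

The Modified Sick Neonatal Score assesses disease severity at admission
from eight bedside parameters, each scored 0 (worst), 1, or 2 (best),
total 0–16. It requires no laboratory investigations beyond a
point-of-care glucose and a pulse oximeter, which is what makes it
usable in district-level newborn care units. Lower totals indicate
higher mortality risk; a total at or below the cutoff (default ≤ 10)
labels the admission high-risk.

| Parameter | 0 | 1 | 2 |
|---|---|---|---|
| Respiratory effort | apnea or grunt | rate > 60/min | rate 40–60/min |
| Heart rate | < 100/min or asystole | > 160/min | 100–160/min |
| Axillary temperature (°C) | < 36 | [36, 36.5) | [36.5, 37.5] |
| Capillary refill (s) | > 5 | 3–5 | < 3 |
| Random blood sugar (mg/dL) | < 40 | 40–60 | > 60 |
| SpO₂ in room air (%) | < 85 | 85–92 | > 92 |
| Gestational age | < 32 w | 32w0d–36w6d | ≥ 37 w |
| Birth weight (kg) | < 1.5 | [1.5, 2.5) | ≥ 2.5 |

Three conventions deserve comment, because the printed rubric bands do
not form a partition on their own:

- **Temperature 36.5 °C** belongs to both printed bands "36–36.5" and
  "36.5–37.5". We resolve the overlap half-open: [36, 36.5) scores 1
  and [36.5, 37.5] scores 2. Each measurement then maps to exactly one
  category, and the shared endpoint goes to the higher category,
  consistent with every other row where the upper label is inclusive.
- **Birth weight "1.5–2.49"** reflects two-decimal recording; we treat
  it as [1.5, 2.5), so 2.499 kg scores 1 and 2.5 kg scores 2.
- **Gestational age** is stored in completed days (weeks·7 + days).
  The middle band is [224, 258] days, so 36w6d (258 d) scores 1 and
  37w0d (259 d) scores 2 with no floating-point week arithmetic.
- **Bradycardia** is operationalized as heart rate < 100/min, the
  complement of the normal band, making the cardiac domain a partition.

Two physiologic regions are genuinely outside the rubric: fever
(> 37.5 °C) and a low respiratory rate (< 40/min) without apnea or
grunting. Silently assigning them a score would fabricate severity in
one direction or the other, so the default **strict** mode raises an
error naming the offending rows. **Lenient** mode scores them
conservatively — fever as 1 (abnormal but not the worst category),
bradypnea as 0 (clinically at least as ominous as tachypnea) — and
records a note in the per-row `warnings` column. Missing values are
never imputed; `msns_score()` refuses the row and names the missing
fields.

## Validation statistics

All of the diagnostic machinery respects the score's orientation:
**low totals indicate the positive (expired) class**, so an
observation is test-positive when its score is at or below the
threshold.

- **ROC and AUC.** `msns_roc()` produces one operating point per
  distinct score plus the (0, 0) endpoint; `roc_auc()` integrates by
  the trapezoid rule. For a discrete score this equals the concordance
  probability P(T₊ < T₋) + ½·P(T₊ = T₋); the test suite verifies the
  identity against direct pairwise enumeration to 10⁻¹² on hundreds of
  random cohorts.
- **AUC confidence interval.** Default Hanley–McNeil (needs only the
  estimate and group sizes), with DeLong's placement-value variance
  available via `auc_ci(method = "delong")`. Both are symmetric normal
  intervals truncated to [0, 1]. Neither was clearly specifiable from
  the original report, so the method is a user-visible choice rather
  than a hidden default; DeLong is cross-checked against pROC in the
  tests.
- **Cutoff selection.** `optimal_cutoff()` maximizes Youden's
  J = sensitivity + specificity − 1 over all thresholds; exact ties go
  to the lower threshold, which is the more specific rule (fewer false
  positives at equal J). A flat curve (max J = 0) is returned flagged
  `informative = FALSE` rather than erroring.
- **Proportion intervals.** Sensitivity, specificity, PPV and NPV carry
  Wilson score intervals. A metric with a zero denominator is reported
  as undefined (`NA`), never 0.
- **Association tests.** `chi_square_test()` is the Pearson statistic
  with expected counts from the marginals and no continuity
  correction; tables with any expected count below 5 are flagged, not
  refused. `mann_whitney()` computes U from midrank sums and the Z
  statistic from the tie-corrected variance
  n₁n₂/12·((N+1) − Σ(t³−t)/(N(N−1))) with **no continuity correction**,
  matching large-sample Z reporting; when the variance is zero
  (all values identical) Z is defined as 0 and p as 1.
- **Summaries.** Group summaries use the sample SD (n − 1) and
  quartiles by linear interpolation between order statistics (R type
  7), the common statistical-package default; the original convention
  is unstated.
- **Multiple testing.** None is applied: per-parameter p-values are
  reported unadjusted, as in the validation study design.
- **Sample size.** `diagnostic_sample_size()` is the Buderer-type
  formula n = ⌈z²·acc(1−acc)/d²/prev⌉ (with 1 − prev in the
  specificity-driven arm, and the maximum of the two under
  `which = "both"`). With anticipated accuracy 0.90, half-width 0.035,
  95% confidence and prevalence 0.5 it returns 565. The published
  calculation does not state its assumed prevalence; 0.5 reproduces the
  planned 565 exactly (1.96²·0.09/0.035² = 282.2, divided by 0.5 and
  rounded up) and is the reconstruction we adopt.

## The synthetic cohort model

`default_cohort_model()` encodes the validation cohort's published
structure: mortality prevalence 95/585, and for each of the eight
parameters the score-category probabilities conditional on outcome,
equal to the published frequency counts normalized within outcome
group. `sample_cohort()` draws the outcome first, then each
parameter's category **independently given outcome**, then a raw
clinical value uniformly from a bounded range lying strictly inside
the category (e.g. tachycardia from 161–220/min, fever is never
generated, respiratory category 0 is realized as apnea with a normal
rate so the rubric-undefined bradypnea region cannot occur).
Re-scoring a generated cohort therefore runs cleanly in strict mode
and recovers every sampled category — an exhaustively tested
round-trip over all 24 (parameter, category) cells. Uniform draws
carry no distributional claim: only the category matters downstream.

Two exact oracles accompany the generator. `exact_total_distribution()`
computes the distribution of the total by convolving the eight
probability triples (identical to enumerating all 3⁸ = 6561
combinations, which the tests do); `analytic_auc()` computes the
concordance probability from the two exact total distributions by a
17 × 17 outer sum. The exact means of the total are 6567/490 ≈ 13.40
(discharged) and 785/95 ≈ 8.26 (expired). The study's own text prints
8.22 for the expired mean — a value computable only from its raw
per-neonate data, which the frequency tables cannot reproduce; we
report the table-implied 8.26 and note the small discrepancy rather
than resolving it.

### What the independence assumption does and does not emulate

Only marginal category frequencies per outcome are published, so
conditional independence is the minimal generating model — it is a
simulation assumption, not a claim about real neonates. Its visible
consequence: real clinical parameters are positively correlated
(a shocked neonate tends to be simultaneously hypothermic, desaturated
and poorly perfused), which makes the total's two outcome
distributions overlap more in real data than under independence. The
synthetic model accordingly discriminates **better** than the real
cohort: analytic AUC ≈ 0.977 versus the ≈ 0.913 observed, and the
exact Youden-optimal cutoff lands at 11 (J = 0.845) with 10 a near-tie
(J = 0.832), rather than the 10 found in the field. Passing tests on
synthetic cohorts therefore demonstrate the correctness of the
scoring and of the statistical machinery, not the field performance
of the score; finite simulated cohorts may select either 10 or 11 as
the empirical optimum, and the tests assert exactly that.

## Numerical choices and problem sizes

Probability triples must sum to 1 within 10⁻⁹; the exact total
distribution conserves mass to 10⁻¹²; AUC–concordance equivalence is
asserted to 10⁻¹². The test suite exercises the generator at up to
n = 50 000 (category-probability recovery within ±0.02 and a
goodness-of-fit check of the total histogram at α = 0.001), empirical
AUC convergence at n = 20 000, and cutoff behaviour at n = 5 000 —
sizes chosen so sampling error is comfortably below the assertion
margins while the whole suite runs in seconds.

## Limitations

- The rubric covers admission-time scoring only; serial scoring,
  maternal and antenatal risk factors, and blood pressure are out of
  scope by design.
- The generator reproduces prevalence and conditional marginals only —
  no inter-parameter correlation, admission-diagnosis mix, referral
  status, or day-of-life structure.
- Field-performance figures (AUC ≈ 0.91, cutoff 10 with 80%
  sensitivity and 88.8% specificity) are properties of the real cohort
  and can only be reproduced against its raw per-neonate data, which
  this package does not ship; the package reproduces every quantity
  derivable from the published summary tables exactly.
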