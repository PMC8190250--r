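---
title: "The VISUAL prognostic score and its validation pipeline: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The VISUAL prognostic score and its validation pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(visualcvid)
```

## The clinical problem

Common variable immunodeficiency (CVID) is an antibody-deficiency disorder
with a very heterogeneous course: some patients have little more than
recurrent respiratory infections, others accumulate bronchiectasis,
autoimmunity, enteropathy, granulomatous disease or malignancy. A
laboratory-only score computed once, at diagnosis, that flags the patients
likely to follow the severe course would let clinicians concentrate
follow-up and early treatment where it matters.

The VISUAL score is such an instrument. It combines five immunological
analytes measured at diagnosis, each mapped to a 1-4 point category by the
magnitude of its alteration:

| Analyte | 1 point | 2 points | 3 points | 4 points |
|---|---|---|---|---|
| smB lymphocytes (% of B cells) | ≥ 6 | [2, 6) | [1, 2) | < 1 |
| Serum IgA (g/L) | ≥ 2SD limit | [0.07, 2SD) | — | < 0.07 |
| Serum IgM (g/L) | ≤ 2.3 | — | — | > 2.3 |
| Specific antibody responses | both adequate | one inadequate | — | both inadequate |
| CD4+ T cells (/µL) | ≥ 700 | [500, 700) | [200, 500) | < 200 |

The total is the plain sum, so it ranges from 5 (all normal) to 20 (all
maximally altered); a total of **10 or more** (inclusive) defines the
high-risk class. `enumerate_visual_combinations()` enumerates all 288
attainable component profiles and is how the package audits this range.

Two categorization conventions deserve a note, because the scoring grid
alone does not fix them and the package had to decide:

* **IgM contributes 1 point when normal.** The grid lists only the
  elevated-IgM cell (4 points). A 0-point convention would make the
  printed 5-20 range arithmetically impossible for a five-analyte sum of
  1-4 categories, so normal IgM scores 1. The elevated threshold is
  2.3 g/L, the upper limit of the normal IgM range (0.4-2.3 g/L).
* **Lower bounds of better categories are inclusive.** smB exactly 6%
  scores 1; CD4 exactly 500/µL scores 2; IgA exactly at the 0.07 g/L
  detectability limit scores 2; VISUAL exactly 10 is high risk. The grid
  labels worse categories with strict "<", which forces this reading.

Values *above* the normal range (CD4 > 1500/µL, smB > 29%) have no
category of their own; they score 1 point and raise a warning flag, since
a hyper-normal value is not evidence of deficiency but may deserve a look.
An incomplete analyte panel is refused with an explicit error; the package
never imputes, because a silently shifted five-component sum would corrupt
the meaning of the 10-point cutoff. The smB normal bound is 6% throughout:
a 10% figure circulates as a descriptive normal level for smB, but the
scoring grid's bound is 6% and the package follows the grid.

The vaccine-response inputs are pre-computed adequacy labels per antigen
class (polysaccharide/pneumococcal, protein/tetanus). When raw titres are
available, `ab_response()` applies the usual criteria (fourfold rise or
0.15 IU/mL for protein; threefold rise or 11 mg/dL for polysaccharide),
but the score itself consumes only the labels, because raw titres are
often unavailable retrospectively.

## Clinical severity: the outcome being predicted

Severity is not observable at diagnosis; it is defined retrospectively
from the complications accumulated over follow-up, under two established
weighting schemes:

* **Ameratunga-style**: each complication graded mild / moderate / severe,
  weighted 1 / 5 / 10; severe evolution ("Cluster B") at a total of 14 or
  more.
* **Grimbacher-style**: 15 complications graded 0-3, the grade being its
  own weight; Cluster B at 5 or more.

The full canonical complication lists are not part of this package's
contract — the arithmetic of weights and cut-offs is. The shipped catalogs
(`inst/extdata/*.yaml`) carry a default item set drawn from the standard
CVID complication spectrum (pneumonia, bronchiectasis, GLILD, autoimmunity,
granulomata, splenomegaly, enteropathy, malignancy, sinusitis,
meningitis/encephalitis, surgery, ...) and are plain editable YAML.

The dichotomization cut-offs (14 and 5) are used as fixed defaults. Because
a clustering algorithm over the observed severity totals could also have
produced them, `two_means_1d()` implements the exact 1-D two-cluster
solution — in one dimension the optimal within-cluster-sum-of-squares
2-partition is always a split of the sorted values, so scanning the n-1
split points is exact, not heuristic — and `silhouette_1d()` reports
silhouette widths (absolute difference on the score line; members of
singleton clusters take width 0). The pipeline reports the data-driven
boundary and its agreement with the fixed cut-off side by side rather than
conflating them.

## Diagnostic performance

`roc_analysis()` evaluates a marker against Cluster B membership with the
orientation *score ≥ threshold predicts severe*. The empirical ROC is
computed over all distinct thresholds; the AUC is the trapezoidal integral,
which equals the Mann–Whitney probability that a random severe patient
outscores a random non-severe one with ties counted one half (the suite
asserts this identity to 1e-12). The optimal cutpoint is the
closest-to-(0,1) criterion: the threshold minimizing
√((1−sensitivity)² + (1−specificity)²), ties broken by higher sensitivity
and then lower threshold. Confusion-matrix ratios with a zero denominator
are reported as missing with an explicit flag, never as 0.

Classifier comparison against the field's routine surrogate — smB
phenotype alone, predicting severe evolution when smB < 2% — uses:

* **McNemar's paired test** for sensitivity (restricted to true severe
  patients) and specificity (true non-severe), with the exact binomial
  two-sided p when the discordant count b + c < 25 and the
  continuity-corrected chi-square otherwise. Zero discordance returns
  p = 1 with a flag.
* **A paired patient-level bootstrap** for the AUC difference: percentile
  interval and two-sided p = 2·min(frac ≤ 0, frac ≥ 0), floored at 1/B.
  Resamples that lose an outcome class are redrawn (capped retries).

Bootstrap intervals throughout are **percentile** intervals (B = 2000 by
default, seed mandatory) — the simplest method consistent with asymmetric
small-sample intervals such as a sensitivity CI whose upper end reaches
100%. Sensitivity/specificity intervals are computed at the cutpoint
selected on the original sample, so they describe the reported operating
point rather than re-optimizing per resample.

## Association statistics

`fit_logistic()` quantifies the per-point association: a
maximum-likelihood logistic fit (IRLS, tolerance 1e-8, at most 100
iterations) of Cluster B on the VISUAL total, reported as the odds ratio
per point with a Wald 95% CI. Complete separation and constant inputs are
explicit errors. Wald rather than profile intervals are used, matching the
symmetric reporting style of the clinical literature.

`odds_at_threshold()` dichotomizes at VISUAL ≥ 10 and delegates to
`fisher_exact_2x2()`, whose two-sided p sums hypergeometric probabilities
no larger than the observed table's. The odds ratio is the sample
cross-product ratio ad/bc; with a zero cell the Haldane–Anscombe 0.5
correction is applied to the OR and CI only (flagged), and a zero margin
makes the test degenerate (p = 1, OR undefined, flagged).

## Progression over age

`km_progression()` estimates the cumulative probability of progression to
Cluster B with the product-limit estimator, on **age** as the time axis
(the natural scale when asking "by what age do high-risk patients
progress?"), stratified by VISUAL ≥ 10 vs < 10 and compared with the
Mantel–Cox log-rank test. Estimation is delegated to the survival package
(`survfit`/`survdiff`); the suite checks the estimator against hand
product-limit computation and, with no censoring, against 1 − ECDF
exactly. Two limitations are deliberate: no left truncation at diagnosis
age (a simple KM on age, so early ages are treated as observed risk time)
and no competing risks. Non-progressors are censored at age at last
follow-up, a required input column.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()` stands in
for them so every pipeline stage is testable. Its defaults are the study
conditions, fixed once:

* n = 50; smB categories at 24/36/14/26%, IgA at 26/24/50%, elevated IgM
  6%, antibody patterns 58/28/14/0%, CD4 strata 44/12/32/12%.
* Continuous lab values drawn uniformly *within* the drawn category's
  interval (smB category 1 on (6, 29)%; IgA category 1 on (0.7, 4.0) g/L;
  IgM normal on (0.4, 2.3) g/L), so re-categorizing the labs reproduces
  the categories for 100% of rows — `roundtrip_check()` verifies this and
  a corrupted-interval hook serves as the negative control.
* Cluster B drawn from a logistic link with per-point log-odds ln(1.3),
  intercept solved in closed form so that P(Cluster B) = 0.56 at the
  expected total (≈ 11.6 under the default marginals).
* Severity totals drawn uniformly on the cluster-consistent side of each
  cut-off (Ameratunga 8-13 vs 14-21, Grimbacher 2-4 vs 5-10) and
  decomposed exactly into complication records, so scoring the records
  reproduces the drawn totals and cluster proportions without error.
* Diagnosis age 4 + 66·Beta(2, 2.6), bounded on (4, 70) with median ≈ 32.
  Progression delay: half immediate, half exponential with mean 4 years
  (overall mean 2, median 0); the late-progression hazard is doubled for
  high-VISUAL patients. Censoring at diagnosis age + Uniform(1, 31) years.
  The delay mixture reproduces the intended mean and median but has a
  wider upper quartile than a real cohort's tightly clustered delays —
  one of several joint features the generator does not attempt.

Analyte categories are drawn independently: only marginal frequencies are
known, and inventing a correlation structure (smB with CD4, say) would
manufacture evidence. Consequently, passing tests demonstrate that the
*machinery* recovers what the generator encodes (marginals, one
association parameter, a hazard contrast) — they cannot certify
performance on real patients, where analytes correlate, severity depends
on more than the score, and follow-up is informative.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite deep but quick:
oracle equivalence uses 100 random ROC instances (n ≤ 200), exhaustive
2-partition search up to n = 12, every 2×2 table with grand total ≤ 30,
and Nelder–Mead likelihood maximization as the logistic oracle (agreement
to 1e-6). Parameter recovery uses 20 cohorts of n = 2000 (mean log-OR
within ±0.1 of ln 1.3), 500 null cohorts for Fisher calibration
(rejection ≤ 7% at α = 0.05), and 500 simulations for bootstrap coverage
(0.95 ± 0.03 on a binomial toy). Pipeline fidelity averages 50 default
cohorts: mean VISUAL AUC must fall in [0.60, 0.85] and beat smB alone in
a majority of seeds — direction-only expectations, because cohort-level
statistics at n = 50 are seed-noisy by nature.

All randomness is funneled through explicit integer seeds
(`withr::with_seed`), and a fixed configuration + seed reproduces every
report byte for byte; the suite asserts this on the written JSON.

## Known limitations

* The default severity catalogs are representative, not canonical; users
  with access to the original item lists should supply their own YAML.
* The generator matches marginals plus one association parameter; joint
  structure, informative censoring and real delay distributions are out
  of scope.
* No covariate adjustment, no Cox regression, no competing risks, no
  DeLong analytic AUC variance (the bootstrap is the comparison method).
* The score's reference limits default to adult ranges; age-adjusted
  limits must be supplied via `visual_reference()` where needed.
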