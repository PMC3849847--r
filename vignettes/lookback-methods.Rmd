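---
title: "Validating lookback-window comorbidity ascertainment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lookback-window comorbidity ascertainment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lookback)
```

## The problem

Hospital discharge collections record diagnoses for administrative
purposes, and comorbid conditions such as diabetes are not reliably coded
on every admission. A study that identifies diabetes from the single
admission it anchors on (the *index admission*) will therefore
underestimate prevalence, and the size of that bias can change when
coding standards change — most notably across the ICD-9 → ICD-10
transition, which in Australia reversed the requirement to code diabetes
irrespective of in-hospital treatment. In *linked* data the natural
remedy is a lookback window: a patient is classified diabetic if any
admission in the `w` years before (or at) the index carries a diabetes
code. This package implements the machinery to validate that design
against a medical-record reference standard, and a synthetic data
generator so all of it can be exercised without access to identifiable
records.

The estimands are the cells of a 2×2 table per stratum and window —
administrative status (test) against the medical record (reference) —
and everything derived from them.

## Cohort and reference standard

- **Index selection.** For each person and sampling era, the earliest
  in-window admission whose *principal* diagnosis is CHD (ICD-9-CM
  410–414, ICD-10 I20–I25, category-prefix match under the record's own
  ICD version). Principal-field-only selection reflects the much higher
  recording accuracy of CHD in the principal field. Same-day ties break
  on the lowest admission id — the paper trail is silent here and
  determinism matters more than the choice.
- **Reference classification.** A patient is reference-positive if
  diabetes is documented *present* in the notes or diabetes drug
  treatment was identified. "Not recorded" with no drugs counts as
  no-diabetes but is flagged, and `drop_not_recorded = TRUE` re-runs
  concordance without those rows (a sensitivity analysis; in the source
  study removing them changed little).
- **Indigenous status.** Record-level Indigenous identification is known
  to be under-reported, so person-level status is derived from the whole
  history: Indigenous iff ≥ 25 % of the person's records are flagged
  (boundary inclusive — 1 of 4 qualifies). The caller controls the
  history horizon by what they pass in; we do not second-guess it.
- **Age eligibility** is a per-era filter (35–79 and 25–79 by default,
  matching the two sampling frames that motivated the design).

Admissions without a reviewable medical-record entry are dropped with a
logged count, mirroring unreviewable notes in practice.

## Ascertainment

Administrative status at window `w` is: the index admission carries a
diabetes code (ICD-9 250 / ICD-10 E10–E14 in any of the 21 diagnosis
fields), OR any prior admission with admission date in
`[index − w years, index)` does. Numerical conventions, chosen once:

- **Half-open calendar windows.** The lower bound is the same month/day
  `w` years earlier (29 Feb → 28 Feb in non-leap years), inclusive; the
  index date itself is excluded from the *prior* scan but always
  contributes through the index term. This makes windows nest exactly, so
  status is non-decreasing in `w` by construction — asserted dataset-wide
  in tests.
- **Admission date** (not separation date) determines window membership.
- **Per-record ICD version.** A 1997 record in the history of a 2003
  index is matched with 250-codes even though the index is ICD-10; the
  version travels with the record, not the cohort.
- Malformed codes never abort anything; they simply fail every match.
- Diabetes-coded admissions dated on/after the index are ignored with a
  warning (they would be a data defect, not a legitimate exposure).

History covariates use the same conventions: `prior_90day` is any
admission in the 90 days before the index; `first_ever_chd` means no
CHD *principal* diagnosis in the prior 15 years. Whether secondary-field
CHD should also disqualify "first-ever" is genuinely open; we use
principal-only for consistency with index selection.

## Concordance measures

From a table `(tp, fp, fn, tn)` with `n = tp+fp+fn+tn`:
sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
NPV `tn/(tn+fn)`, observed agreement `(tp+tn)/n`, and Cohen's kappa
`(p_o − p_e)/(1 − p_e)` with
`p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)]/n²`. All are reported ×100;
presentation rounding is **half away from zero** to 1 decimal
(`round_half_away()`), matching how published tables round. A measure
with a zero denominator is `NA`, never silently 0.

The net **under/over-estimation** statistic is
`(Sensitivity/PPV − 1) × 100`. Algebraically `sens/ppv =
(tp+fp)/(tp+fn)`, so this is exactly the relative difference between the
number of test-positives and reference-positives:
`(fp − fn)/(tp + fn) × 100`. Negative values mean the administrative
source undercounts true cases; the identity is asserted numerically in
the test suite.

### Statistical comparisons

- **Paired prevalence** (administrative vs reference, same patients):
  McNemar's test, large-sample form `(fn − fp)²/(fn + fp)` on 1 df with
  no continuity correction; below 25 discordant pairs we switch to the
  exact two-sided binomial test on the discordant pairs. Zero discordant
  pairs returns `p = 1` by convention.
- **Between independent samples** (e.g. the ICD-9 vs ICD-10 eras): each
  rate measure is compared by Pearson chi-square (no continuity
  correction) on the measure's own numerator/denominator split —
  sensitivity compares `tp|fn`, specificity `tn|fp`, and so on.
- **Under/over-estimation between samples** has no textbook test; it is
  a ratio. Our construction: a two-sample z on `log(sens/ppv)` —
  equivalently `log(test-positives) − log(reference-positives)` — with
  delta-method variance treating the four cells as multinomial, which
  gives `var = 1/A + 1/B − 2·tp/(A·B)` with `A = tp+fp`, `B = tp+fn`.
  A seeded percentile bootstrap (`bootstrap_under_over_diff()`, 2000
  resamples by default) is provided as a cross-check; neither is claimed
  to be the construction used in any particular publication. The z-test's
  type-I error is checked by simulation under the null in the test suite.

## Misclassification predictors

False negatives (`reference-positive ∧ administrative-negative at the
index`) are modelled among reference-positives; false positives among
reference-negatives — each outcome is `NA` outside its group so it
cannot leak into the wrong denominator. Covariates are banded as in
validation practice (length of stay 1–2/3–5/≥6 days, age 25–50/51–65/
66–79, Charlson 0/1–4/≥5, comorbidity count 0–3/4–7/≥8), with reference
levels set to the conventionally reported baselines (emergency
admission, no in-hospital death, ≥6-day stay, other CHD, ≥8
comorbidities).

- **Screening**: per-variable Pearson chi-square, switching to Fisher's
  exact test when any expected cell count is below 5 (the conventional
  rule; "small cell counts" has no sharper published definition in this
  context). Degenerate variables are skipped with a message.
- **Modelling**: variables significant at `entry_p` (0.05 by default;
  0.1 as the sensitivity variant) enter a maximum-likelihood logistic
  model with Wald 95 % CIs on the odds ratios. The glm convergence
  tolerance is tightened to 1e-12 so a single-covariate model reproduces
  the contingency-table cross-product ratio to 1e-8 (a test invariant).
  Separation/non-convergence is flagged on the result and warned about,
  never silently reported. If nothing screens in — typical for false
  positives, which are rare — no model is fitted at all.
- Age and sex are *not* forced into the models when non-significant;
  forcing them is a defensible alternative, but the default stays with
  screening-driven entry.

**Charlson index.** No installed package provides an ICD-mapped Charlson
score, so the package ships a Quan-style ICD-9-CM/ICD-10 prefix mapping
of the 17 conditions with the original weights (`charlson_map()`),
applying the standard severity hierarchies (complicated diabetes over
uncomplicated, moderate/severe liver over mild, metastatic over any
malignancy) — which also makes the score monotone under code-set
inclusion. Diabetes is excluded by default since it is the condition
under validation. The index is computed from all 21 diagnosis fields of
the index admission (so an MI principal contributes its weight 1); the
comorbidity *count* is the number of non-diabetes secondary fields.

## The synthetic data generator

`sim_config()` defaults describe a two-era validation cohort:

| parameter | default | why |
|---|---|---|
| era sizes | 1685 / 2258 | the two sampling frames' published sizes |
| era windows | 1998; 2002–04 | ICD-9 and ICD-10 sampling periods, cutover 1999-07-01 |
| Indigenous proportion | 1.5 % / 23.2 % | the later frame oversampled Indigenous patients |
| reference prevalence | 22.5 % (ICD-9); 28.5 % non-Indigenous / 56.2 % Indigenous (ICD-10) | back-calculated from published stratum margins |
| per-admission coding sensitivity | 0.90 (ICD-9 records) / 0.80 (ICD-10 records) | index-admission sensitivity ≈ this parameter; the ICD-10 drop reproduces the coding-directive change |
| miscode probability | 0.013 / 0.018 | matches the published false-positive rates at index |
| admission rate | 0.4/person-year, ×1.5 if diabetic | multi-year histories with higher hospitalization in diabetics; the true rate distribution is unpublished, so this is a free parameter, not an estimate |
| `p_record_indigenous` | 0.7 | record-level Indigenous under-identification |
| `p_not_recorded` | 0.025 | "not recorded" reference entries among non-diabetics |

The admission process is homogeneous Poisson per person over the history
window (15 years by default); each record's ICD version follows its own
date; a coded diabetes admission puts the code in a uniformly chosen
secondary field (principal fields are reserved for the admission's own
reason); the medical record is truth by default (`p_doc_present = 1`),
so concordance estimands equal the coding parameters and parameter
recovery is testable — e.g. with coding probability `p` and `K` prior
admissions in the window, detection probability is `1 − (1−p)^(K+1)`,
whose expectation over a Poisson count (`expected_lookback_sensitivity()`)
is the analytic oracle the Monte-Carlo tests check against.

Two deliberate simplifications matter for interpretation. First, **one
index-eligible CHD admission per sampled era is guaranteed**: prior
admissions never receive a CHD principal code dated inside an era
sampling window (outside the windows they may, exercising the
first-ever-CHD covariate). Second — and most importantly — **per-admission
coding is independent given true status**. Real coding is correlated
within a patient (a diabetic who is never coded stays never-coded), which
is why published sensitivities plateau around 90 % at 10–15-year
lookbacks, while the independence model drives simulated sensitivity
toward 100 % and piles up miscode false positives as the window grows.
The simulation therefore reproduces the *qualitative* pattern
(sensitivity rising, specificity and PPV drifting down with lookback) and
exact parameter-recovery identities, not any real study's numeric
trajectory — passing tests show the pipeline's arithmetic and plumbing
are right, not that the generator mimics a particular population.

Determinism: one integer seed drives the whole generation through an
isolated RNG scope (`withr::with_seed`), so the same configuration and
seed reproduce the output tables exactly, and no global RNG state leaks.

## Problem sizes in the test suite

Unit and property tests run on hand-built histories and simulated cohorts
of a few hundred persons per era. The statistical guarantees use the
sizes at which their tolerances are meaningful: parameter recovery and
the Monte-Carlo-vs-closed-form check at 20 000 persons (within 3 binomial
SE), kappa and chi-square against brute-force oracles on 1000 random
tables (1e-12), logistic CI coverage of a known OR = 3 effect over 500
replicates, and the z-test's size over 500 null replicates. All seeds are
fixed in the tests.

## Known limitations

- Probabilistic record linkage is out of scope; `person_id` is trusted.
- The generator's independence assumption (above) understates how hard
  long-lookback PPV erosion is to avoid in real data, and overstates
  sensitivity gains.
- Charlson mapping choices differ across publications; the shipped
  Quan-style table is one defensible mapping, exposed as data so users
  can substitute their own.
- Kappa confidence intervals are not computed (not needed for the
  reports this package produces).
- How dual-frame patients' duplicate records should be reconciled in
  real collections is study-specific; synthetic persons are sampled per
  era, so the question does not arise here.
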