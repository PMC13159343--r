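---
title: "Margin-threshold scanning with multiplicity control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-threshold scanning with multiplicity control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginscan)
```

`marginscan` asks whether the width of a negative surgical resection
margin, in millimetres, carries prognostic information for local
recurrence in a myxofibrosarcoma registry cohort — and, just as
importantly, quantifies how fragile any apparent cutoff is. This vignette
documents the statistical procedures, the deterministic cohort
reconstruction, the synthetic-data generator, and the design decisions
taken where the problem left genuine freedom.

## The threshold scan

The exposure is the minimum tumour-to-ink distance; the outcome is binary
local recurrence. Dichotomizing a continuous exposure at a data-chosen
cutoff and testing the resulting 2×2 table is the classic
maximally-selected-statistic situation: the more cutoffs are examined, the
more the smallest p-value overstates the evidence. The scan makes the
whole procedure explicit:

1. **Candidate cutoffs.** Under the default `distinct_observed` rule the
   candidates are the distinct observed margin values; a candidate `c`
   splits the cohort into `margin < c` versus `margin ≥ c` and is
   admissible when both groups contain at least `min_group_size` patients.
   The default `min_group_size = 6` is the smallest value under which the
   canonical cohort yields exactly its eight published candidate cutoffs
   (0.2–1.0 mm): at 1.0 mm the upper group has 6 patients (admissible),
   at 2.0 mm only 5 (not).
2. **Per-cutoff test.** Each table is tested with the two-sided Fisher
   exact test under the point-probability rule: the p-value sums the
   conditional hypergeometric probabilities of all tables with the same
   margins that are no more likely than the observed one. Point
   probabilities are computed in log-space and compared with a relative
   tolerance of 1e-7 so that ties are not broken by floating round-off.
   Mid-p and twice-one-sided variants are available but are not the
   default, because the point-probability rule is the convention under
   which the published per-cutoff p-values reproduce exactly.
3. **Bonferroni.** `p_bonf = min(1, m · p_unadj)` with `m` the number of
   admissible cutoffs. Valid but blunt here: the nested cutoff tables are
   strongly positively correlated, so Bonferroni overcorrects.
4. **Min-p permutation FWER.** Outcome labels are permuted against the
   fixed margin vector `B` times (default 5000); each permutation
   recomputes the full p-value vector across all admissible cutoffs and
   records its minimum. The adjusted p at cutoff `j` is the add-one
   fraction `(1 + #\{min_b ≤ p_j\})/(B + 1)`. This estimates the
   family-wise error exactly under the permutation null while respecting
   the correlation structure, and is therefore the appropriate correction
   for a nested scan.

Numerical and reproducibility choices: permuted p-values are obtained from
a precomputed lookup table indexed by the number of events below each
cutoff, so a scan costs `O(B·n)` rather than `O(B·m·n)`; records are
canonically sorted by margin and outcome before permuting, making the
result invariant to input row order at a fixed seed; ties between a
permuted minimum and the observed p count toward "at or below"
(conservative); the add-one estimator guarantees a strictly positive,
valid p, with the plug-in ratio available as an option. A degenerate table
(empty row or column, e.g. when all labels agree) returns p = 1 with a
warning. The continuous profile (`scan_profile()`) evaluates the
unadjusted p on a fixed grid (default 0.1–6.0 mm by 0.1) with no group
size filter; it is flagged multiplicity-unadjusted and is for inspection
only.

## The canonical cohort reconstruction

No patient-level data are shipped or required: the canonical cohort is
forced, almost everywhere, by the published summary tables, and
`validate_reconstruction()` re-derives every printed cell from the
reconstruction (53 checks). The constraints and the few genuinely free
choices:

* The nested below-cutoff group sizes at the eight cutoffs (20, 24, 26,
  27, 28, 29, 30, 32 of 38) fix the one-decimal histogram of margins
  below 1 mm, including the 20-patient point mass at the 0.1 mm floor.
  Each bin `[x, x + 0.1)` is represented by its left endpoint; the two
  patients in `[0.8, 1.0)` are both set to 0.8 rather than 0.8/0.9 so the
  distinct observed values admit exactly the eight published cutoffs; the
  1–5 mm category is spread as 1, 2, 3, 4, 5 mm and the single
  above-5 mm margin is 8.0 mm (forced by the printed range 0.1–8.0).
  Under linear interpolation between order statistics (quantile type 7,
  the convention that recovers the printed upper quartile 0.575), the
  sorted 28th and 29th values are 0.5 and 0.6 and the 75th percentile is
  0.5 + 0.75·0.1 = 0.575 mm exactly.
* Successive differences of the below-cutoff recurrence column force the
  per-bin events: 10/20 at 0.1 mm, 2/4 at 0.2 mm, 0/8 in 0.3–0.8 mm,
  1/6 at ≥ 1 mm. Which individuals within a bin carry the events is
  exchangeable and irrelevant to every implemented statistic; a fixed
  deterministic assignment is used.
* Radiotherapy within the fine-margin stratum is published only at the
  stratum level (20 treated with 6 recurrences, 12 untreated with 6). A
  naive smallest-margin-first fill would put all 20 treated patients at
  0.1 mm and violate the stratum's treatment-by-outcome cells, so the
  fill runs smallest-margin-first *within each outcome class*, with
  quotas of 6 recurrent and 14 non-recurrent treated patients. Any rule
  meeting the quotas leaves the scan and the stratified tables unchanged,
  but logistic/ROC outputs that use radiotherapy on the subcohort do
  depend on it — they are therefore reported as assignment-dependent and
  no published model coefficient is treated as a reproduction target.
* Grade and the prior-external-surgery flag match published marginal
  totals only (18/28/33/5 and 36/11/37, with prior surgery concentrated
  among margin-undocumented patients), assigned in id order; they feed no
  statistic.

Two published figures are knowingly not matched because they are
internally inconsistent with the published cross-tabulation: the category
recurrence rates "33%" (1–5 mm; the table gives 1/5 = 20%) and "25%"
(missing; the table gives 15/41 ≈ 37%), and the crude radiotherapy
contrast "27% vs 43%" (complete-case counts give 25.0% vs 42.6%). The
package reproduces the table; `rt_crude_comparison()` reports the
count-derived rates with a confounding-by-indication caveat.

## The synthetic registry generator

`simulate_cohort()` exists so every stage can be exercised at arbitrary
sample size with known truth. Per subject: a standard-normal latent risk
`z`; a margin drawn from a mixture of a point mass at 0.1 mm (probability
`floor_mass = 0.53`, the observed 20/38) and a log-normal
(`meanlog = -0.45`, `sdlog = 1.2`) rounded to one decimal and floored at
0.1 — parameters chosen once so the mixture's upper quartile sits near
0.575 mm, by moment-matching the 18 non-floor reconstructed values;
radiotherapy with probability `plogis(qlogis(0.38) + 0.8·z)`
(confounding by indication: treatment follows risk); recurrence from
`plogis(-0.35 + log(0.85)·margin + log(0.52)·rt + frailty_sd·z)`, the
effect directions and the baseline matching the reported per-mm
association, adjusted treatment effect and ≈35% crude recurrence; margin
missingness with marginal probability 0.55 (shifted by prior external
surgery, which occurs with probability 0.43) and recurrence-status
missingness 0.06. All defaults are declared stand-ins for an unknown
generative process, fixed in one place, and never tuned to any test.

What the generator emulates: the floor point mass, one-decimal coding,
missingness linked to external surgery, and treatment-by-indication. What
it does not: follow-up time, re-resection pathways, tumour size/depth
effects, or any real-data correlation beyond the latent frailty — so
passing tests validate the *procedures*, not clinical conclusions.

Two testable consequences anchor the design. First, with
`gamma_confound > 0` and a null treatment effect, the crude comparison is
biased *against* treatment (treated subjects carry higher latent risk) —
the suite demonstrates this artefact, which is the reason the package
never reports a crude radiotherapy contrast without a caveat. Second,
`parameter_recovery()` checks that the logistic stage recovers generating
coefficients with nominal Wald coverage. That requires the identifiable
regime `gamma_confound = 0` *and* `frailty_sd = 0`: an unmodelled
frailty attenuates marginal logistic coefficients (by roughly
`1/sqrt(1 + 0.346·σ²)`), which is a feature of the generator, not an
estimation bug, so the recovery experiment switches the frailty off
rather than pretending conditional and marginal effects coincide.

## Exploratory model layer

The logistic stage fits recurrence on a margin term (continuous per mm, or
dichotomized at a chosen cutoff) and radiotherapy by iteratively
reweighted least squares, keeping the per-iteration log-likelihood trace
(non-decreasing by construction; asserted in tests), Wald standard errors
from the observed information, convergence at relative log-likelihood
change below 1e-10 (max 100 iterations), weights clamped at 1e-10, and a
quasi-separation flag at |coefficient| > 15 on the log-odds scale. The
ROC layer computes the curve over all distinct score thresholds, the AUC
by trapezoid — identical to the Mann–Whitney concordance with half credit
for ties, an identity the tests assert to 1e-10 — and the Youden-optimal
threshold with ties broken toward higher specificity. For a margin-only
model the Youden threshold is mapped back to millimetres by inverting the
monotone linear predictor; for multi-predictor models it is reported on
the score scale only, since a probability cutoff then has no unique
margin equivalent.

The bootstrap stage resamples patients with replacement (percentile
summaries at 2.5/50/97.5%; non-converged, separated or single-class
resamples counted and excluded; the whole report flagged unreliable above
50% failures). On the canonical subcohort with the margin dichotomized at
0.3 mm, about a third of resamples are quasi-separated — the probability
that the single above-cutoff event is absent from a resample is
`(1 − 1/38)^38 ≈ 0.36` — and the converged odds ratios span well over an
order of magnitude. This is the instability the analysis exists to
expose: with 13 events, the dichotomized-margin odds ratio is not a
stable quantity, and the package intentionally reports dispersion and
failure counts rather than a single headline interval. Published
multivariable coefficients, AUC and Youden values from the original
five-covariate model are not reproduction targets: the extra covariates
are not reconstructible at patient level, and on the two-predictor model
the corresponding quantities are assignment-dependent.

## Problem sizes and known limitations

The validation suite runs the full scan at B = 5000 for the headline
permutation p-value (its Monte-Carlo standard error at p ≈ 0.03 is
≈ 0.0024, so seed-to-seed variation of a few thousandths is expected and
estimates are pooled over three seeds), B = 500 over 200 null replicates
of 60-patient synthetic cohorts for family-wise-error validity, and 100
replicates of 20 000-subject cohorts for coverage — sizes at which the
Monte-Carlo error of each check is small relative to its tolerance.
Remaining limitations are inherent to the data, not the implementation:
within-bin assignments make subcohort treatment-adjusted models
non-unique; the five unknown recurrence statuses are never imputed; no
time-to-event structure exists, so no survival modelling is attempted;
and the exact test's conservatism means the scan's power at 38 patients
is modest under any correction.
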