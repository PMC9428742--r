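---
title: "Methods: polygenic risk, physical activity, and gestational diabetes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk, physical activity, and gestational diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdrisk)
```

# The scientific problem

Gestational diabetes (GD) affects roughly 7% of US pregnancies, and its
strongest predictors — adverse outcomes in prior pregnancies — are undefined
for nulliparous women. Two measurable risk factors remain: genetic
predisposition, summarized as a type-2-diabetes polygenic risk score (PRS),
and physical activity in early pregnancy, summarized as weekly metabolic
equivalents of task (METs). `gdrisk` implements the full analysis pipeline
for studying their joint association with GD in a nulliparous cohort:
genotype quality control and PRS computation, METs scoring and activity
dichotomization, GD case definition from glucose tolerance tests, subgroup
contingency statistics with bootstrap inference, a gene–environment
interaction logistic model, and a cross-validated prediction harness. A
synthetic-data generator reproduces the statistical structure of the study
population so that every stage is testable without access to the restricted
cohort data.

# Case definition

GD status is determined from glucose tolerance tests (GTT), with thresholds
compared inclusively ("at least") in mg/dL:

* fasting 3-hour 100-g GTT: positive with **two or more** abnormal values
  among fasting ≥ 95, 1 h ≥ 180, 2 h ≥ 155, 3 h ≥ 140 (the
  Carpenter–Coustan pattern);
* fasting 2-hour 75-g GTT: positive with **one or more** abnormal values
  among fasting ≥ 92, 1 h ≥ 180, 2 h ≥ 153 (the IADPSG pattern);
* non-fasting 50-g screen: positive at ≥ 200 mg/dL, and **only counted when
  no fasting GTT was performed**.

A clinical diagnosis is used only in the absence of GTT data; when both are
present and disagree, the GTT wins. When a participant carries both a 100-g
and a 75-g fasting test, each is evaluated independently and GD is reported
if either qualifies — the source protocols do not state a precedence, and
this "either qualifies" rule is the interpretation adopted here. No unit
conversion happens internally; `mgdl_to_mmoll()` (× 0.0555) is display-only.

The eligibility cascade removes, in order: participants missing all
covariates, prediabetes, pre-pregnancy diabetes, participants with no GD
determination (no GTT and no clinical diagnosis), missing/invalid METs, and
missing PRS. The per-step counts are reported so the filter is auditable;
the cascade is idempotent, and step counts always sum to the number of rows
removed. Ancestry-based eligibility is represented only as an opaque
caller-supplied flag: ancestry inference is out of scope.

# Genotype QC and the polygenic score

Variant-level filters retain variants with missingness ≤ 0.02, minor allele
frequency ≥ 0.01, and exact Hardy–Weinberg p ≥ 1e-6. The HWE test is the
standard exact (Levene–Haldane) test on hard calls, without a mid-p
correction — the community default that a bare p-value threshold presumes.
Sample-level filters retain samples with call rate ≥ 0.98 and |F_het| ≤ 0.2,
with F_het = 1 − observed/expected heterozygosity, the expectation summing
2p(1−p) over the variants called in that sample. All statistics are
recomputed from the calls; input metadata is never trusted.

One practical caveat the synthetic runs make visible: on a small panel (the
84 PRS variants alone), F_het has standard deviation ≈ 0.1, so the |F| ≤ 0.2
rule removes ~10–15% of perfectly good samples. The filter presumes
genome-wide variant counts; when scoring from a pre-extracted panel,
`qc_filter_samples()` should be applied to the full genotyping array, or its
threshold relaxed deliberately.

Imputation-quality filtering applies only to imputed variants: genotypes
whose maximum posterior probability is not above 0.80 are set to missing,
and variants with INFO ≤ 0.1 or MAF ≤ 0.005 are dropped. The posterior rule
is ambiguous between per-genotype and per-variant readings in the source
description; the per-genotype reading is the default, with the per-variant
aggregate available via `per_variant = TRUE`.

The PRS is the unstandardized weighted sum of risk-allele dosages,
`score_i = Σ_v β_v · dosage_i(effect allele at v)`. Orientation is resolved
by allele identity against REF/ALT (flipping the dosage when the effect
allele is REF); variants whose alleles match neither orientation are dropped
and reported, and if fewer than half of the weight variants match, scoring
aborts — that failure mode almost always means a genome-build or naming
mismatch, and silently scoring the remainder would be worse than stopping.
Strand-ambiguous palindromic pairs (A/T, C/G) are matched by identity with a
warning rather than by frequency-based strand inference: curated panels of
this size are expected to be strand-consistent, and allele-frequency
inference is unreliable near 0.5. Missing dosages are imputed as twice the
cohort effect-allele frequency, keeping scores comparable across samples.

Quartile assignment cuts at the 25th/50th/75th percentiles (R's default
type-7 quantiles); a score exactly at a cut point goes to the lower bin,
which is deterministic and matches rank-percentile convention. A constant
score vector degenerates to all-Q1 with a warning.

# Activity scoring

Total weekly METs is the weighted sum of activity minutes:
`Σ intensity × sessions/week × minutes/session`, in MET·min/wk. Intensities
are caller-supplied per activity (a small compendium-style default table
ships with the package) because the source questionnaire's weights are not
printed. The activity dichotomization uses 450 MET·min/wk — equivalent to
150 minutes of moderate (3.0 MET) or 75 minutes of vigorous (6.0 MET)
activity per week — with the boundary classed as *more active*
(`mets ≥ 450`), mirroring the "METs ≥ 450" / "METs < 450" subgroup labels.

# Subgroup statistics

Every subgroup analysis reduces to a 2×2 table of GD cases and controls
inside and outside the subgroup.

**Odds ratio.** OR = (cases_in/controls_in)/(cases_out/controls_out), with a
95% Woolf interval, `exp(log OR ± 1.96 √(Σ 1/cell))`. The Woolf interval
reproduces every printed interval in the published subgroup tables at one
decimal except a single lower bound (the age ≥ 35 row, where the printed 2.1
is not reproduced by Woolf, exact-conditional, or Haldane-corrected
intervals — all give 2.0 from the printed counts; a double rounding
2.045 → 2.05 → 2.1 upstream is the most plausible explanation). Zero cells
trigger the Haldane–Anscombe +0.5 correction, flagged in the result. The
p-value is the two-sided Fisher exact test under the conventional rule (sum
of probabilities of tables at most as probable as the observed one), and is
cross-checked in the tests against full hypergeometric enumeration.

**Positive likelihood ratio.** LR = posterior odds / prior odds of
diagnosis, where posterior odds are the subgroup's case/control odds and
prior odds come from the reference group — the whole cohort, or, for nested
comparisons, the parent subgroup's own counts.

**Bootstrap inference.** Participants are resampled with replacement
(`n_boot` = 10 000 by default); each replicate recomputes the child
subgroup's LR against the whole replicate cohort, and the parent's where a
parent exists. Internally the resampling is a multinomial draw over the
joint (child, parent, GD) strata — exactly equivalent to row resampling,
since rows within a stratum are exchangeable, and fast enough to keep
10 000 replicates routine. The reported p is the proportion of replicates in
which the child LR falls on the null side of the reference (1 for the whole
cohort; the parent's replicate LR for nested comparisons), with ties
counting 0.5 — unbiased under the exchangeable null. Replicates with an
empty subgroup are dropped and counted, with a warning past 10%. The 95% CI
is the percentile interval of the child-LR replicates; quartile/activity
labels are frozen attributes, not recomputed per replicate (memberships are
fixed characteristics of the reconstructed participants; recomputing cut
points per replicate is a different estimand and is deliberately not done).

**Direction of the one-sided p.** By default the null side is chosen from
the observed comparison ("lower or higher, as appropriate") — the adaptive
rule of the source analysis. A consequence worth stating plainly: under an
exchangeable null the adaptive p is uniform on (0, 0.5), so rejecting at
α gives a type-I rate of 2α. Simulation confirms rejection ≈ 0.09 at
α = 0.05. For calibration experiments the direction must therefore be fixed
a priori (`direction = "greater"` or `"less"`), for which the p is uniform
on (0, 1) and the test is exact — the calibration acceptance test does
exactly this, and the adaptive doubling is itself asserted as a property.

**Count expansion.** `from_counts()` and `expand_family()` turn printed
contingency counts into individual-level rows carrying categorical flags, so
printed tables can be bootstrapped and fitted like raw data. Marginal tables
recomputed from the expansion equal the inputs exactly; inconsistent nesting
(child counts exceeding the parent's) is a named validation error. One
printed inconsistency is resolved in favor of the table body: the joint
table's footnote quotes the low-activity LR as 1.4 where the body prints 1.3
(the computed value is 1.346).

# The interaction model

The interaction test is an ordinary maximum-likelihood logistic regression

$$\mathrm{logit}\,P(Y=1) = a + b\,X_1 + c\,X_2 + d\,X_3 + e\,X_4 + f\,X_3X_4,$$

with \(X_1, X_2\) age and BMI (confounder-adjusted variant only), \(X_3\)
the top-quartile PRS indicator, \(X_4\) the low-METs indicator, and the Wald
z-test on \(f\). The source description appends a Gaussian ε inside the
logit; that term is nonstandard in a Bernoulli likelihood and is dropped —
the fit then reproduces the printed coefficients exactly (a = −3.5,
d = 0.42, e = 0.12, f = 0.82, p = .03 from the printed joint counts), which
is the justification for the reading. Its variance σ² is accordingly not
estimated. The unadjusted model on two binary covariates is saturated:
fitted probabilities equal empirical cell proportions, and the coefficients
equal closed-form cell log-odds contrasts, which the tests assert
independently of the IRLS path. Convergence uses a log-likelihood change
below 1e-8 within 100 iterations; unstable coefficients (|coef| > 15) are
reported as a separation error rather than returned.

The adjusted model cannot be validated against printed values — age and BMI
are individual-level and unavailable from counts — so it is validated by
parameter recovery on synthetic cohorts: at n = 50 000 and the published
effect scale, the mean bias of \(\hat f\) across 100 replicates is below
0.05 (an acceptance test).

# Prediction harness

`evaluate_model()` runs stratified k-fold cross-validation (default 10
folds), pools out-of-fold scores, computes the AUC by the rank (Mann–Whitney)
statistic with midrank tie correction, and takes the 95% CI from a bootstrap
(default 100 iterations) over the pooled out-of-fold (score, label) pairs.
Whether the source bootstrap resampled folds or participants is unstated;
pooled-pair resampling is the choice here and is documented as such. The
default classifier is an L2-regularized logistic regression with C = 1
(glmnet ridge, λ = 1/(nC)) — the source never names its model, so this is
recorded prominently as an assumption, and any
`(x_train, y_train, x_test) → scores` function can be passed instead.
Baseline features follow the adapted screening-question set: age, BMI,
race/ethnicity indicator, family history of diabetes, PCOS, hypertension,
and waist circumference, with pregnancy history and HbA1c omitted (both
undefined or unavailable for nulliparous participants). Missing waist is
median-imputed with a missingness indicator. The published AUCs
(0.710/0.734/0.708/0.728) require the restricted cohort and are *not*
reproduction targets; the harness is validated by properties — exact AUC
oracles, separation and null behavior, and the ordering that an informative
PRS never degrades the baseline beyond fold noise.

# The synthetic world

`simulate_cohort()` draws a cohort whose marginals are fixed once, from the
published descriptive statistics where available:

| quantity | value | basis |
|---|---|---|
| cohort size | 3533 | published analysis cohort |
| GD prevalence | 0.037 | published (132/3533); intercept solved to the target |
| age | N(28.6, 4.9²) yr | published mean (SD); implies P(age ≥ 35) ≈ 0.10, matching the 365/3533 margin |
| BMI | N(24, 4.4²) kg/m² | chosen so P(BMI ≥ 25) ≈ 0.41, the 1453/3533 table margin |
| METs | lognormal(6.428, 0.865²) | mean ≈ 900, SD ≈ 950 MET·min/wk; right-skewed with SD ≈ mean as the printed case/control means imply; gives P(METs < 450) ≈ 0.35 vs the 1168/3533 = 0.33 margin |
| family history | Bernoulli(0.18) | back-derived from the (45+591)/3533 margin |
| PRS panel | 84 variants, freq ~ U(0.05, 0.95), β ~ \|N(0.1, 0.04)\| | gives a raw score with mean ≈ 8.4 and SD ≈ 0.6, the printed scale |
| outcome | logit with b = 0.10, c = 0.08, d = 0.41, e = 0.10, f = 0.78 | the published adjusted coefficients |

Genotypes are drawn variant-wise Binomial(2, freq) with non-palindromic
allele pairs; the PRS is computed through the same `compute_prs()` the real
pipeline uses, and the top-quartile and low-METs flags come from realized
values. One global seed fans out to fixed per-component child seeds, so
adding a component never perturbs earlier draws; output is byte-identical
under a fixed seed. `inject_missingness()` masks entries completely at
random and returns the truth mask, which the QC and eligibility tests use as
an oracle.

What the generator does **not** emulate: linkage disequilibrium between
variants, ancestry structure, longitudinal visits, reporting error in
activity logs, and any correlation between covariates beyond what the
outcome model induces. A green end-to-end test therefore establishes that
the pipeline recovers the generative structure it is pointed at — not that
the published effect estimates are correct.

A power note recorded here because it shapes a test: at the published
effect scale the activity main effect (e = 0.10) is genuinely weak — its
analytic sign-recovery power at n = 20 000 is only ≈ 85% — so the end-to-end
sign-recovery test asserts ≥ 95% recovery for d and f and a correspondingly
lower bound for e, rather than pretending the stated world has power it
lacks.

# Numerical choices and degenerate inputs

* Thresholds are inclusive exactly as printed; boundary METs = 450 is
  *more active*; boundary quartile scores go to the lower bin.
* Zero 2×2 cells: Haldane +0.5 for OR/CI (flagged); a fully zero margin is
  an error. A subgroup with no controls yields LR = +Inf with a warning.
* Bootstrap ties count 0.5; replicates with empty subgroups are dropped and
  counted.
* The intercept solve for the prevalence target uses `uniroot` on
  [−50, 10]; an unreachable target is an explicit error.
* Seeds are plain 32-bit integers; helper functions save and restore the
  caller's RNG state.

# Known limitations

* The subgroup analysis applies no multiplicity correction across the
  subgroup family, matching the source analysis; the family of ~27
  comparisons should be read accordingly.
* The adaptive bootstrap direction doubles the nominal type-I rate (see
  above); fixed-direction tests are available and used for calibration.
* `from_counts()` reconstructs only the categorical structure the counts
  determine; continuous covariates of reconstructed participants are absent
  by construction.
* The sample-QC F_het rule is miscalibrated on small variant panels (see
  the QC section).
* PRS scoring assumes a curated, strand-consistent weights panel;
  palindromic variants are matched by identity, never by frequency.
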