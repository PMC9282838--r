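---
title: "Methods: epigenetic age acceleration in newborn methylation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epigenetic age acceleration in newborn methylation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoclocks)
```

# Overview

`neoclocks` analyses newborn blood DNA methylation for evidence of
accelerated epigenetic aging, with two-group (Down syndrome vs non-DS)
cohorts as the motivating design. The pipeline takes normalized beta-value
matrices as input — array preprocessing (functional/noob normalization,
BMIQ, IDAT parsing) is deliberately out of scope — and covers clock
computation, age-acceleration derivation, reference-based cell-type
deconvolution, array-based trisomy 21 dosage calling, and the inferential
model suite. A synthetic-cohort generator with complete ground truth closes
the loop for testing.

# Clocks and the calibrated transform

A clock is `x = a + sum_j w_j beta_j` over its CpG set. Two output
conventions exist in the field and both are supported:

* **Calibrated age clocks** (pan-tissue- and skin-and-blood-style): the
  linear predictor is mapped to years by the anti-transform
  `(1+A) exp(x) - 1` for `x < 0` and `(1+A) x + A` for `x >= 0`, with
  anchor age `A = 20` years. The transform is continuous and strictly
  increasing with fixed point `A` at `x = 0`. The anchor is the single
  canonical choice of the original calibration; it is not re-estimated
  here, and the same anchor is used for both age clocks (whether the
  published skin-and-blood calibration ever used a different anchor is not
  documented in the sources this package follows).
* **Gestational age clocks**: the predictor is already in days and is
  returned untransformed.

**Missing-CpG imputation.** Clocks trained on older array platforms lose
probes on newer ones. Absent clock CpGs (and per-sample missing entries)
are replaced by the *per-sample mean over that sample's available clock
CpGs* — the rule is stated in words in the methods literature accompanying
these clocks, and mean replacement reproduces it exactly and
deterministically. A k-nearest-neighbour variant was considered and not
implemented: it would introduce a tuning parameter and an external
dependency without a documented reference behavior. A sample with zero
available clock CpGs is an error naming the sample, not a silent NA.

**Restricted clock variants.** Sensitivity analyses drop clock CpGs on the
trisomic chromosome 21 and CpGs shared with the deconvolution reference.
`restrict_clock()` removes them from the weight map entirely — the
restricted clock never reads those CpGs (verified by a corruption test) —
rather than imputing them, and the CpG overlap is always computed from the
loaded clock and reference objects, never hard-coded.

# Age acceleration

DNAmAA is the residual of clock value on chronological age (gestational age
plus age at blood collection, days from conception), where the line is
fitted by OLS *in the non-DS reference group only* and residuals are taken
for every sample. The reference-group mean is therefore exactly zero — a
property the tests assert at `1e-9` — and the DS-group mean acceleration is
an unconfounded group contrast on the clock scale. Samples missing
chronological age are excluded from both the fit and the residuals, with
the count logged; no imputation of ages is attempted.

Effect estimates in clock units are converted to days by dividing by the
reference slope (`estimate_to_days()`), applied identically to point
estimates and CI bounds. By default the *unrounded fitted slope* is used;
`pipeline_config(paper_slope = 0.001)` selects the reporting convention in
which published day values are exact multiples of a rounded 0.001/day
slope. Per-clock reference lines are fitted independently.

Gestational clocks use a different anchor: residuals from
`clock ~ gestational_age + DS` fitted on all samples. The two anchors
coincide exactly when the DS effect is zero and collection age is constant
(tested). Because the gestational anchor regresses DS out, the generator's
gestational clocks carry no DS signal and the downstream DS contrast on
gestational acceleration is null by design — mirroring the biological
finding the design emulates.

# Cell-type deconvolution

Proportions over seven cord-blood cell types (B, CD4T, CD8T, NK, Mono,
Gran, nRBC) are estimated per sample by nonnegative least squares against
reference mean-beta profiles (Lawson–Hanson NNLS via `pracma::lsqnonneg`),
then normalized to sum to one. The cited reference-based method leaves
totals unconstrained; post-hoc simplex normalization is adopted here
because the proportions feed regressions as compositional covariates.
Identifiability requires a full-row-rank reference; rank deficiency is an
error at construction. The tests compare the NNLS solution against an
exhaustive simplex grid search (0.01 step over every support of up to three
cell types, plus a 0.05-step grid over the full 7-simplex) and require
agreement within 0.02 per component; the grid oracle shares no code with
the NNLS path.

Samples whose nRBC proportion exceeds 25% are flagged (`flag_high_nrbc()`,
strict inequality, applied to the normalized proportions — the sources do
not state whether the rule preceded normalization, and normalized is
adopted). High-nRBC samples distort genome-wide methylation and are
excluded in a sensitivity subset. Granulocytes, the dominant and
compositionally determined fraction, are the dropped category in all
regressions; passing `Gran` as a covariate is an error rather than a silent
near-collinearity.

# Trisomy 21 dosage calls

Per-bin log2 copy ratios are `log2(intensity / median reference intensity)`
with a seeded random draw of disomic newborns as reference
(`select_cnv_reference()`, seed logged). The chromosome 21 summary is the
median over its bins (317 by default). Calls for DS-labelled samples:

1. **likely mosaic/partial**: median more than `sd_mult = 2` SDs (n−1
   denominator; the sources do not specify, and the sample SD is adopted)
   below the DS-cohort mean *and* above the maximum non-DS median. Cohort
   statistics include the candidate mosaics themselves.
2. **full T21**: otherwise, median `>= 0.2`.
3. **not elevated**: otherwise — kept with a QC warning rather than
   dropped; the sources are silent on this case.

The mosaic rule takes precedence where the rules overlap, consistent with
observed flagged medians (0.08–0.18) sitting below the full-trisomy
threshold. The 0.2 threshold itself reflects array compression of the
theoretical full-trisomy shift `log2(3/2) = 0.585`; the generator models
that compression with a multiplicative `attenuation` (default 0.5, giving
full-T21 medians near 0.29). Classification is order-invariant, and fixed
cohort statistics can be supplied to apply a frozen rule to new samples.

# Association models

The model layer is ordinary least squares throughout, with Wald 95%
confidence intervals from the t distribution (the CI method is not stated
in the sources; Wald-t is the conventional choice for OLS).

* **Covariate screening**: candidates are kept when their univariable
  regression against the outcome *in the non-DS group* gives p < 0.2
  (overall F test, so multi-level factors screen as a unit). Constant
  candidates are skipped with a warning; an empty survivor set falls back
  to exposure-only models.
* **Ancestry PCs**: the number of PCs is the smallest k minimizing AIC over
  the nested sequence PC1..PCk (k = 0..10), ties toward smaller k, with
  likelihood-ratio p-values reported alongside. The clock and acceleration
  outcomes may legitimately select different k; the pipeline reports its
  own selected counts and never hard-codes them.
* **Model structure**: chronological age is a covariate if and only if the
  outcome is a clock (acceleration is already age-independent); gestational
  age replaces chronological age for gestational-clock outcomes. The full
  model adds six of seven cell proportions (granulocytes dropped). Batch is
  a categorical fixed effect.
* **Subset rules**: `exclude_high_nrbc` (nRBC > 25% removed),
  `gata1_wildtype_plus_nonds` (DS restricted to GATA1-wildtype),
  `ds_only`. A subset that leaves a single exposure level is an error, as
  is an aliased design (reported with the offending columns).
* **GATA1 models**: mutation status among sequenced DS newborns, and VAF
  among mutation-positive newborns only; days per 10% VAF is
  `estimate * 0.1 / slope`. With fewer than 3 mutation-positive samples the
  VAF model is skipped with a warning; with too few mutants to support the
  covariates it is fitted unadjusted, again with a warning.
* **Bivariate layer**: Student's t (continuous), chi-squared (categorical),
  Spearman for clock-age correlations, and Kruskal–Wallis with BH-adjusted
  pairwise Wilcoxon tests for the three-level T21 comparison. Multiplicity
  control beyond the BH pairwise procedure is out of scope. Raw p-values
  are always stored; `format_p()` implements the conventional `< 1e-4`
  reporting floor as formatting only.

# The synthetic cohort generator

`simulation_config()` defaults encode the study conditions the package is
designed around: group sizes 346/567; gestational age 266.98 (SD 17.65) vs
274.47 (13.93) days; collection age 55.25 (49.74) vs 32.72 (17.46) days;
birthweight 3029.90 (686.27) vs 3386.10 (541.77) g; 17% high-nRBC DS
subset; 16% GATA1-mutant fraction among the ~53% of DS newborns with
sequencing; DS clock offset 0.24 years; age slope 0.001 years/day; VAF
slope 1.78 years per unit VAF; attenuation 0.5 over 317 chromosome 21
bins. The baseline intercept −0.676 places non-DS clock values near −0.40
at the mean non-DS chronological age.

Mechanics worth knowing:

* **Age signal embedding.** For each clock the target output is converted
  to its linear predictor (inverting the calibrated transform where
  needed) and the deviation from a 0.5-baseline predictor is distributed
  across CpGs proportionally to `w_j / sum(w^2)`, so applying the clock
  returns the target exactly. `generate_synthetic_clock()` sizes weights so
  the whole newborn range (−1 to 2 years; 150–320 days for gestational
  clocks) is attainable with betas inside [0, 1]; clipping, when a
  user-supplied clock forces it, is counted and reported, never silent.
  At `noise_sd_beta = 0` the closed loop recovers truth to 1e−8 (machine
  precision in practice).
* **Collection age is gamma-distributed**, matched to the configured mean
  and SD. A zero-truncated normal — the naive reading of "mean 55, SD 50,
  nonnegative" — would inflate the realized mean by roughly 12 days in the
  DS group; the moment-matched gamma keeps support nonnegative, both
  moments exact (sample moments recover configured values within 3 SE at
  n ≥ 1000 per group, tested), and a realistic right skew for bloodspot
  collection delays. Gestational age and birthweight are truncated normals
  with physiologic bounds (150–320 days; 300–6500 g) far enough in the
  tails to leave moments intact.
* **Cell mixtures** are Dirichlet draws around cord-blood means
  (granulocyte-dominated), with the DS shift pattern — lower B, CD4T,
  Gran, Mono; higher CD8T, NK, nRBC — applied to the DS concentration
  vector. The high-nRBC subset gets nRBC re-set to 27–50% with the other
  six types rescaled, and GATA1-mutant samples are assigned to that subset
  first, reproducing the nRBC–GATA1 confounding structure that motivates
  the sensitivity analyses.
* **Noise model**: i.i.d. Gaussian noise of SD `noise_sd_beta` (default
  0.01) added to every beta and clipped to [0, 1]; the within-cohort split
  of clock variance between measurement and biology is not documented for
  this design, so the noise SD is a free parameter and 0.01 (clock-scale
  SD ≈ 0.06 for a 30-CpG unit-scale clock) was chosen once as a realistic
  post-normalization array noise level.
* **Dosage signal**: chromosome 21 bins are shifted by
  `attenuation * log2((2 + f)/2)` with `f = 1` (full), the mosaic cell
  fraction, or 0; bin noise SD defaults to 0.05. Other chromosomes provide
  a disomic baseline.
* **Determinism**: everything derives from the config seed; identical
  configs give bit-identical cohorts (tested via `identical()`).

What the generator does **not** emulate: probe-level chemistry and batch
effects, genome-wide CpG correlation structure outside the clock /
deconvolution / chromosome-21 sets, nonlinear age trends, and any coupling
between cell composition and clock CpGs beyond the GATA1 VAF term.
Passing tests therefore demonstrate that the *analysis chain* is correct
and calibrated under its stated model — not that the biological effect
sizes would be recovered from raw arrays, which is exactly why the QC and
sensitivity machinery exists.

# Numerical and testing choices

* Betas outside [0, 1] are clipped with a logged count wherever they can
  arise (embedding, noise injection); validated containers reject
  out-of-range inputs outright.
* QC order is fixed and documented: detection-p filter (mean p > 0.01),
  then CpG missingness > 15%, then sample missingness > 15% computed after
  CpG removal (the source ordering is unstated; this order is adopted and
  tested).
* AIC ties break toward fewer PCs; `which.min` on the nested sequence
  implements this as the first minimum.
* The BH step-up is delegated to `stats::p.adjust` and checked in tests
  against hand-derived vectors. (BH is monotone but *not* idempotent —
  re-adjusting an adjusted vector can change it — so idempotence is
  deliberately not asserted.)
* Test problem sizes were chosen once for statistical resolution: 200
  cohorts of 200+200 for CI coverage of the injected 0.24 offset (accepted
  band 0.92–0.98), 1000 cohorts of 50+50 for type-I error (band
  0.03–0.07), 50 cohorts for mosaic flagging across fractions 0.2–0.5,
  and reduced bin counts wherever the dosage signal is not the quantity
  under test.

# Known limitations

* Published clock coefficient sets are consumed via a documented CSV
  schema but not redistributed; analyses of real cohorts must supply them.
* The deconvolution reference is an input; selecting an optimal reference
  CpG library from sorted-cell data is out of scope.
* Mosaic and partial trisomy cannot be distinguished from array dosage
  alone; the call label says so.
* The model layer is OLS only — no mixed effects, survival, or mediation —
  and gestational clocks are treated as fixed predictors, not retrained.
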