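---
title: "Methods: signature discovery for Kashin-Beck disease blood profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature discovery for Kashin-Beck disease blood profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbdsig)
```

## The design being modeled

Kashin-Beck disease (KBD) is an endemic osteochondropathy whose clinical
diagnosis is reliable only in advanced disease. The pipeline in this
package targets the matched-pair, two-color microarray design used to
search for a blood-based signature: each of 100 KBD cases (50 clinical
degree I, 50 degree II) is paired with an age- and sex-matched healthy
control; the control cRNA is labeled Cy3 and the case cRNA Cy5, both
hybridized to one 169-gene custom array; the quantity carried forward is
the per-pair, per-gene intensity ratio (case over control). Discovery then
proceeds in stages: differential-expression screening, mutual-information
feature ranking, a leave-one-out support-vector-machine wrapper that sweeps
signature sizes, independent test-set evaluation, and a Bayes discriminant
for disease degree.

## Statistical model, stage by stage

**Preprocessing.** Spots with a negative quality flag are discarded. Per
spot and channel, the background estimate is subtracted from the foreground
and the result floored at a positive constant (default 1 intensity unit) so
ratios stay defined. One multiplicative constant per array then rescales
the Cy5 channel. Two estimators are exposed because the right choice
depends on the differential load:

* `"sum"` — total-intensity balance (the Cy5 sum is made equal to the Cy3
  sum). Unbiased only when up- and down-regulation cancel in total
  intensity.
* `"median"` — the median spot-wise Cy5/Cy3 ratio is set to 1. Robust as
  long as under half the spots are differential; with this panel (50 of
  169 genes differential, net direction down) the median estimator is the
  better default for real use, and `run_pipeline()` uses it.

With either method the recovered matrix equals the true ratios up to one
constant per array; on the default synthetic panel that constant deviates
from 1 by a few percent. This is an intrinsic property of global
normalization under asymmetric differential expression, not an
implementation artifact, and the tests assert exactly that decomposition
(exact within-array constancy, bounded constant).

**Differential screening.** Per gene the package reports the mean and SEM
of the per-pair ratios on the ratio scale (the convention of the field's
tables), and tests the log2 ratios against zero with a two-sided
one-sample Student t-test — the natural paired analogue when each array
already encodes a within-pair comparison. Adjustment is Bonferroni over
the genes actually tested (genes lost to missingness are flagged, not
silently dropped, and do not count toward the correction). A gene is
called up if mean FC > 2 *and* adjusted p < 0.05, down if mean FC < 0.5
under the same significance condition. Calls are monotone in both
thresholds by construction.

**mRMR.** Mutual information needs discrete states; the discretization is
the classic three-state scheme: per gene, values below mean − k·sd map to
−1, above mean + k·sd to +1, else 0 (k = 1 by default). MI is the plug-in
estimate in bits with no small-sample bias correction — the estimator of
the methodology this stage follows; its small-sample optimism is uniform
across candidate genes at a fixed step, which is what matters for an
argmax. Selection is greedy: the first gene maximizes relevance
I(gene; label); step k maximizes relevance minus the mean MI with the
already-selected set (MID). The quotient form (MIQ) is selectable and
divides by max(mean redundancy, 1e-12). Ties break toward the lower gene
index so rankings are deterministic.

**SVM wrapper.** Features are z-scored with training statistics (scales
floored at 1e-8), and a linear C-SVC is fit via LIBSVM. Only the linear
kernel is offered: a kernel-width parameter is inert in a linear kernel,
so the cost C is the sole hyperparameter, tuned on the grid 2^-5, 2^-3,
..., 2^15 by seeded 5-fold cross-validation with ties going to the
smallest C. The leave-one-out sweep holds one sample out, rebuilds the
feature pool and the mRMR ranking from the remaining samples only, fits
one SVM per signature size, and predicts the held-out sample; selection,
discretization thresholds, standardization, and cost search never see the
held-out sample. Two pool protocols are supported: fully nested
re-screening per fold (`de_first = TRUE`), and a fixed pool supplied once
(`pool =`), which reproduces the historical protocol of screening on the
full cohort before the wrapper. The fixed-pool protocol is what makes the
model count exact — 160 folds x sizes 1..50 = 8000 SVM fits — while the
nested protocol is the one whose leakage behavior the test suite verifies
(pure-noise cohorts stay at chance accuracy; ranking outside the fold
demonstrably inflates it).

**Final signature.** With 160 folds there are 160 slightly different
rankings; the shipped resolution is to run mRMR once on the full training
set and take the top n (default 20), while reporting per-fold selection
frequencies alongside so the stability of each member is visible. The
accuracy-versus-size curve is always returned; choosing compactness over
the last fraction of a percent of accuracy is left to the user.

**Degree discriminant.** Classification of degree I vs II uses a Gaussian
linear discriminant on the log2 ratios of the signature genes: per-class
means, pooled within-class covariance with denominator (n − k), priors
equal by default (matching the balanced 50/50 design; proportional priors
are available). Log2 rather than raw ratios because multiplicative noise is
approximately Gaussian there. If the covariance is ill-conditioned a ridge
term (1e-6 of the mean diagonal, escalated tenfold until the Cholesky
factorization succeeds) is added and recorded on the fit. Posterior ties
resolve deterministically to degree I. "Original" tables are
resubstitution; "cross-validated" tables refit with each case left out.

**Orthogonal validation.** Relative qPCR quantification is plain
2^−ΔΔCt: per sample, technical replicates are averaged, ΔCt = Ct(target) −
Ct(housekeeper); ΔΔCt = mean ΔCt(case) − mean ΔCt(control). No
amplification-efficiency correction is attempted. The group comparison is
a Mann-Whitney rank-sum test: exact by full enumeration of rank
assignments up to combined n = 20 (valid under ties via mid-ranks),
normal approximation with tie-corrected variance and continuity correction
beyond. Age checks per gene are a Pearson correlation of log2 ratio
against age and a one-way ANOVA across four groups at the sample age
quartiles (the quartile boundaries are reported with the result).

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the statistical structure the
analysis assumes, so that every downstream stage has a planted ground
truth:

* **Panel.** 169 genes; 50 differential (18 up, 32 down). The 20
  signature-panel genes carry their published mean fold changes
  (0.21–0.49 down, 2.39–4.26 up); the 30 differential genes that the
  published table does not name get deterministic fold changes spaced over
  the same ranges and clearly synthetic symbols (`KBDU##`, `KBDD##`);
  null genes are `NULL###` with FC 1.
* **Noise.** i.i.d. Gaussian noise on log2 ratios with a single SD
  (default 0.3), split evenly between the case and the control profile of
  a pair. A single-SD model is the simplest one consistent with reporting
  only a mean ± SEM per gene; gene–gene correlation is deliberately absent
  (see limitations).
* **Effect planting.** Because the reported statistic is the arithmetic
  mean of per-pair ratios, differential genes are planted with log2 mean
  log2(FC) − sd²·ln2/2, which cancels the lognormal mean bias exactly:
  the expected sample-mean ratio is the planted FC. Null genes stay
  centered at log2 ratio 0 so the paired t-test is exactly type-I
  calibrated on them; their ratio-scale mean (≈ 1.02 at sd 0.3) is far
  inside any calling threshold.
* **Degree substructure.** Nothing in a case/control ratio design
  identifies how degrees I and II differ, so this is a synthetic-only
  assumption: a configurable gene subset is shifted by ±effect/2
  (degree II up, degree I down) with an exact mean-preserving correction,
  so the between-degree separation is the configured effect while the
  marginal case/control fold change — the quantity the screen and the
  recovery tests consume — is untouched. The default subset is the five
  up-regulated signature genes: their fold changes sit several sigma from
  the calling thresholds, so degree structure cannot corrupt the planted
  differential truth, while still giving the degree discriminant a
  realistic, imperfectly separable signal.
* **Ages and sexes.** Case ages uniform on 43–79 years, control ages on
  40–77 (the reported cohort ranges), independent of expression by
  default — matching the reported absence of age effects — with an
  optional `age_trend` knob that plants a linear per-year log2 slope in
  one gene for negative-control tests.
* **Scans.** Per pair, one two-channel spot table with lognormal per-gene
  baseline intensities (log2 uniform on 8–14, shared across arrays as
  probe affinity), additive Gaussian background (mean 100, SD 10), a
  channel-wide multiplicative Cy5 dye bias (default 1.5) so normalization
  is non-trivial, and a configurable bad-spot fraction (default 2%,
  GenePix-style negative flags).
* **Ct tables.** Target Ct = 25 cycles in controls plus the planted ΔΔCt
  in cases; housekeeper fixed at 18 cycles; measurement noise SD 0.2
  cycles; group sizes 5 + 5 by default, mirroring the validation cohort
  scale.
* **Seeds.** One master seed; every stage derives an independent child
  seed deterministically, so identical configs reproduce cohorts, scans
  and Ct tables byte for byte.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: gene–gene correlation (co-regulation would
make mRMR's redundancy term do real work; here it mostly re-ranks noise),
spatial or print-tip artifacts, dye-swap designs, intensity-dependent
(lowess-type) bias, batch effects, and any systematic difference between
degree groups beyond the configured mean shift. Recovery of the planted
counts shows the machinery is correct at the published effect sizes and a
plausible noise scale, not that real cohorts of this size will reproduce
the published accuracies.

## Numerical and policy choices

* Background-corrected intensities are floored at 1 so ratios and logs are
  always defined; the floor is configurable.
* Genes missing in more than 20% of pairs are dropped from the panel with
  a warning; remaining missing cells are excluded pairwise from per-gene
  statistics; for the degree discriminant (which needs complete rows) the
  pipeline fills missing cells with the gene's median ratio.
* Genes with fewer than 3 usable pairs are reported flagged with call
  "ns" rather than dropped, and are excluded from the Bonferroni count.
* A constant ratio of exactly 1 yields p = NA and "ns" (no sampling
  variability, textbook null); a constant ratio different from 1 yields
  p = 0.
* The train/test split assigns whole pairs (80 train / 20 test by
  default), because the differential screen consumes complete pairs; this
  reproduces an 80/80 + 20/20 sample design while keeping the pairing
  intact. Splits are either seeded or given explicitly, never implicit,
  and are validated disjoint before any stage runs.
* One deliberate borderline: one published down-regulated fold change
  (0.49) sits one noise-SD from the 0.5 calling threshold at the default
  noise level, so its call flips in a minority of synthetic replicates.
  This is a property of the planted value, not of the screen.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
the sizes the design specifies where the quantity checked demands it (100
pairs x 169 genes for the recovery checks; 160 training samples x sizes
1..50 for the 8000-model count) and at reduced sizes for property checks
(null calibration over 200 cohorts of 20 pairs; optimism and fuzzing
properties over dozens of small replicates). The full suite completes in
about a minute on one CPU.

## Known limitations

* The mRMR stage assumes independence-ish features when interpreting the
  redundancy penalty; with strongly co-regulated real genes the selected
  set depends on the discretization width k.
* The plug-in MI estimator is biased upward at small n; since the bias is
  shared across candidates at each greedy step this rarely changes the
  argmax, but reported criterion values should not be read as unbiased
  information estimates.
* Global normalization by sums or medians cannot remove
  intensity-dependent dye bias; arrays needing lowess-type correction are
  out of scope.
* The degree discriminant is linear with a shared covariance; strongly
  heteroscedastic degree groups would call for a quadratic rule, which is
  deliberately not offered.
* 2^−ΔΔCt assumes perfect and equal amplification efficiency for target
  and housekeeper.
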