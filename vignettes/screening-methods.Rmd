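---
title: "Screening virgin olive oil grades from GC-MS volatile fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening virgin olive oil grades from GC-MS volatile fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The screening problem

Commercial grading of virgin olive oil into extra virgin (EVOO), virgin
(VOO) and lampante (LOO) is a sensory judgement: trained panels score the
fruity attribute and the defects (rancid, fusty-muddy,
musty-humid-earthy), and the grade follows from the median defect
intensity — no perceived defect for EVOO, a defect median up to 3.5 for
VOO, above 3.5 (or no fruitiness) for LOO. Panels are a scarce resource.
An instrumental screening tool can absorb most of the workload if it
assigns the clear-cut samples automatically and defers only the boundary
ones back to the panel.

`olivescreen` implements such a tool for untargeted volatile
fingerprints: the raw total-ion chromatogram (TIC) of a headspace GC-MS
run, used directly as a feature vector without peak identification or
quantification. The pipeline is

1. TIC extraction (CSV or mzML, scans before minute 5 dropped) and
   interpolation onto a common retention grid;
2. retention-time alignment, per analytical batch and then globally;
3. analytical QC: noise-window estimation, signal gating, per-scan RSD
   repeatability, PCA distance-to-model diagnostics;
4. PCA outlier screening (Hotelling's T², Q residuals), then two
   cascaded binary PLS1-DA models with ROC-derived uncertainty bands;
5. repeated stratified holdout validation with per-category and
   per-defect reports.

## Retention-time alignment

The aligner is an interval correlation-optimised shifter in the icoshift
style. The scan axis is partitioned into `n_intervals` equal contiguous
intervals (default 50). Per sample and interval, the integer shift within
`[-max_shift, max_shift]` that maximises the Pearson correlation with the
reference segment is applied; vacated positions are filled with the
nearest retained boundary value. Defaults follow the published icoshift
conventions scaled to our grid: the reference is the column-wise mean
chromatogram, and `max_shift` is 10% of the interval length. Pearson
correlation (rather than raw cross-covariance) makes the objective
scale-invariant across samples of very different total intensity.

Two choices are ours. Ties between equally good shifts go to the
smallest absolute shift, then to the negative one, so output is
deterministic and distortion minimal. And a per-row guard reverts a row
to its unshifted state if its whole-row correlation with the reference
would decrease: per-interval optimisation cannot otherwise guarantee
row-level monotonicity, and the guard makes "alignment never degrades
coherence" an invariant rather than a tendency.

For large studies the aligner runs in two stages (`align_batched`):
each analytical batch is first aligned to its own mean — within-batch
shifts are small, so short searches suffice — and the pre-aligned
ensemble is then aligned to the global mean. Batches with one sample
skip stage 1 with a message.

## In-house validation of the fingerprint

Untargeted fingerprints have no analyte-wise validation, so the method's
repeatability is assessed on the signal itself:

* **Noise.** The mean and SD of the baseline are estimated on the
  contiguous window (at least 300 scans, configurable) with minimal
  variance — an automatic proxy for "a representative peak-free region".
* **Gating.** A scan point is kept when the mean replicate intensity
  strictly exceeds mean noise + 3 SD. Gating is monotone: raising the
  threshold never adds points.
* **RSD.** For each retained point, the relative standard deviation
  percent across pooled-QC replicate injections, benchmarked at the
  15% (and 20%) analytical-variability convention. Points with zero mean
  are reported as undefined and excluded from the fractions rather than
  mapped to 0 or infinity.
* **Distance to model.** A PCA (unit-variance scaled, mean centred) of
  QC replicates plus the control oils; each sample's normalized residual
  SD is `sqrt(RSS_i/(p - A))` divided by the model's pooled residual SD.
  The default critical value comes from the F distribution at 95% on
  that ratio; because plotting conventions in some chemometrics software
  place this cut at other values (e.g. a normalized 0.05), a fixed
  override is accepted and reported verbatim. Both behaviours are
  exposed; neither is guessed to be canonical.

System suitability uses the same noise estimate: S/N of named marker
compounds is `(apex - mean noise)/noise SD` with a pass above 3, and the
resolution of a close-eluting pair is `R = (t2 - t1)/((w1 + w2)/2)` with
the baseline width `w = 4 sigma` from a local Gaussian (log-quadratic)
fit, pass at `R >= 1`.

## Chemometrics

All multivariate stages operate on unit-variance scaled, mean-centred
data. Zero-variance columns get scale 1 — they become exactly zero and
stay inert — instead of being dropped, which keeps column indexing
aligned with the scan axis. Preprocessing statistics are always learned
on training rows only and reapplied to held-out rows.

**PLS1-DA.** A NIPALS PLS1 regression of a 0/1 class dummy: per latent
variable `w = X'y/||X'y||`, `t = Xw`, `p = X't/(t't)`, `q = y't/(t't)`,
with deflation of X (and y). Coefficients are accumulated per LV count,
so one fit predicts at any smaller number of components. At full rank
PLS1 reproduces the least-squares solution, which the tests exploit as
an oracle.

**Model selection.** Leave-10%-out cross-validation with seeded,
stratified folds (the fold seed is part of the model record). Per LV we
report `PRESS`, `RMSEcv = sqrt(PRESS/n)` and `Q² = 1 - PRESS/TSS` with
TSS about the global mean of y (the per-fold-TSS variant exists in some
software; the global form is what this package records). The LV count
minimises RMSEcv, ties resolved towards fewer components (parsimony);
the default cap of 10 comfortably covers the 5-7 LV range typical for
this problem.

**Diagnostics.** Overfitting and chance correlation are checked by
permutation tests (default n = 20; both the empirical p-value
`(1 + #[Q²_perm >= Q²]) / (n + 1)` and the strict "original exceeds all
permuted" flag are reported) and by an ANOVA on the cross-validation
residuals: `F = ((SS_null - PRESS)/A) / (PRESS/(n - A - 1))`, upper-tail
p from the F distribution, clamped to F = 0, p = 1 when the model does
no better than the mean. A model with Q² <= 0.4 or CV-ANOVA p >= 0.05 is
flagged, not rejected — the screening thresholds below remain valid
either way, only less useful.

**Outlier screening.** PCA by SVD; Hotelling's T² with the F-based limit
`A(n-1)(n+1)/(n(n-A)) F(A, n-A)` and Q residuals with the
Jackson-Mudholkar limit. A sample exceeding either limit at 95% is
flagged before classification modelling, mirroring the usual workflow.
One caveat the tests document: a gross rank-one corruption of a training
row inflates the leading components themselves and is then caught by T²
rather than by the residual statistics — distance-to-model QC detects
deviations that do not dominate the model.

## The hierarchical cascade and its uncertainty bands

Two binary models in sequence: model 1 separates EVOO (dummy 1) from
non-EVOO on all training rows; model 2 separates LOO (dummy 1) from VOO
and is fitted — with its own preprocessing — on the true non-EVOO
training subset only, since it is an independent PLS-DA.

Each model's reject band comes from its ROC curve over the
cross-validated predicted values (PV): the **lower threshold** is the
smallest PV among true positives (sensitivity 1 at or below it) and the
**upper threshold** the largest PV among true negatives (specificity 1
above it). Samples with PV inside the closed interval are *uncertain*
and deferred to the panel; a PV exactly on a threshold defers — the
conservative reading of a boundary case. By construction, every training
sample outside the band is correctly assigned out-of-fold; the fit
asserts this invariant every time.

When the classes separate perfectly in CV the band is empty
(lower > upper). We then collapse to a single midpoint threshold between
the highest negative and the lowest positive PV, classifying at-or-above
as positive. Published tables in this field print a single threshold in
that situation without defining it; the midpoint is this package's
convention, not an inference of anyone else's rule.

At screening time, model 1 assigns EVOO (PV above its band) or passes
the sample to model 2 (PV below); samples uncertain at model 1 go
straight to the panel and model 2 is not consulted, following the
decision flow of the two-step strategy.

## Validation harness

External validation repeats a seeded stratified 80/20 split (default 7
times, per-split seeds spawned from one master seed and recorded). The
training count per category is `round(0.8 n)` with halves rounded up —
which reproduces exactly the published 98/86/57 + 24/22/14 partition of
a 122/108/71 study. Alignment is fitted on the full matrix before
splitting, as is standard for this workflow (alignment is unsupervised
and label-free); the leakage guard therefore covers preprocessing, PLS
and thresholds, and refuses validation rows that were trained on.

Reports follow the conventional layout: per category and in total, the
percent uncertain, percent assigned, percent correctly classified *of
the assigned*, and the *reliable assignment* percent, which counts
deferred samples as resolved correctly by the panel (the panel being the
reference method). Aggregates are means and SDs over splits; the total
correct-of-assigned row uses the assigned-count weighted mean and SD.
Undefined percentages (zero denominators) are reported blank, never as
0. The per-defect breakdown tabulates, per main perceived defect, the
uncertainty rate, survival of model 1 (assigned and not called EVOO,
over assigned) and VOO/LOO correctness among the samples model 2
actually assigned — the published tables leave those denominators
implicit; this package defines them as the true-class samples among
model-2 assignments and always prints the count pairs alongside.

## The synthetic-fingerprint generator

Real sensory-graded sample sets of this size are not public, so the
package ships a forward model that emulates the statistical structure
the pipeline assumes:

* a fixed library of 17 marker volatiles (hexanal, 1-hexanol,
  (Z)-3-hexenyl acetate, (E)-2-heptenal, pentanoic acid and other
  defect/fruity markers) as Gaussian peaks on the retention axis —
  Gaussian because no peak-shape information is published for this
  method and it is the simplest shape supporting resolution and S/N
  arithmetic; widths are 2-10 scans at the default grid;
* log-amplitudes linear in the sample's sensory attributes (fruity
  median plus the main defect's median), so defect intensity acts
  multiplicatively on marker abundance — consistent with oxidation
  volatiles being present across categories at different concentrations;
* lognormal biological spread (SD 0.25 on the log scale), additive
  baseline noise (5% of baseline within day, 3% day effect), per-sample
  retention jitter (SD 1.5 scans) and a systematic 3-scan shift per
  batch;
* a VOO/LOO cut at defect median 3.5 (the trade convention), with a
  configurable fraction (default 13%) of non-EVOO samples drawn within
  ±0.5 of the cut and flagged as boundary samples;
* pooled QC replicates built from the arithmetic mean of the control
  oils' noise-free amplitude vectors (two EVOO, four LOO controls by
  default); replicates re-draw only analytical noise — multiplicative
  with 5% CV — plus, in inter-day mode, a day-level response factor and
  day-level retention jitter. Biological spread is never re-sampled per
  replicate.

The default grid is 2000 points over minutes 5-58.4; the
instrument-resolution grid (16,347 points) is one configuration change.
Effect sizes are free parameters: no quantitative mapping from sensory
medians to volatile concentrations is published, so the simulator's
class separation is a chosen study condition, not an estimate of the
real system. Consequently, passing tests demonstrate that the *machinery*
is correct and that the workflow recovers known structure under
realistic noise — they say nothing about classification rates on real
oils, which the original study had to measure empirically. Two further
honest gaps: the generator produces TICs only (no m/z-resolved
structure, no mass-spectral fragmentation) and no chemical kinetics of
oil ageing; and its inter-day repeatability under the default day
effects sits below the intra-day one by construction, so the two QC
modes give materially different RSD profiles.

## Numerical choices and degenerate inputs

* Noise-window search: exhaustive over contiguous windows via running
  sums; ties go to the earliest window.
* Sub-scan information is never interpolated during alignment — shifts
  are integer scans, edges padded with the boundary value.
* Correlations of zero-variance segments are treated as minus infinity
  (such segments never shift).
* An empty uncertainty band uses the midpoint threshold; `>=` assigns
  the positive class there.
* `n_perm = 0` skips permutation testing (used to keep repeated-split
  runs fast); any permutation run requires `n_perm >= 1`.
* Degenerate dummies (one class), empty datasets, non-monotone retention
  axes, grid mismatches at prediction time and validation/training
  overlap all fail fast with named errors.

## Problem sizes in the test suite

The suite exercises the full pipeline at reduced sizes chosen for quick
iteration: unit fixtures use 400-1000-point grids and 30-60 samples;
model-behaviour fixtures are drift-free, because at coarse grids the
peak widths fall below one scan and retention jitter would alias them —
drift handling is exercised by the alignment tests and by the end-to-end
run, which simulates the full 305-sample design (122/108/75, three
defects, two batches) on the 2000-point grid, aligns per batch, screens
outliers and validates over seven splits.
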