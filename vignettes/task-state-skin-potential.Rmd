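---
title: "Task-state skin potential analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-state skin potential analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptask)
```

## The problem

Skin potential (SP) is the endogenous electrical potential measured
between two skin sites, a component of electrodermal activity driven by
sympathetic sudomotor tone. The clinical protocol this package
reimplements records SP at 5 Hz while participants from three groups —
bipolar depression (BPD), major depressive disorder (MDD) and healthy
controls (HC) — view six emotion-inducing stimulus tasks. From each
task-state recording, 18 features are extracted (10 time-domain, 8
band-energy), the 108-column per-participant matrix is compared across
groups feature by feature, a balanced-subsample RBF-SVM discriminates
the groups under leave-one-out cross-validation (LOOCV), and SP
features are screened for correlation with blood oxidative-stress
markers within the patient groups.

The clinical recordings are not publicly deposited, so the package
pairs the analysis pipeline with a synthetic cohort generator whose
structure is fully known. All quantitative claims about the pipeline
are made against that generator or against published summary artifacts
(confusion matrices, per-group summary statistics), never against
unavailable raw data.

## The feature set

For each task, `max` and `min` are taken from the cleaned series in mV;
all other measures are computed after per-task min–max normalization to
$[0,1]$: the median (`n50`), mean, sample variance, RMS, and the mean
and sample SD (both with the $n-1$ convention) of the first- and
second-order differences.

The eight band energies `freq0`…`freq7` cover the contiguous
0.0625 Hz-wide bands spanning 0–0.5 Hz. A dyadic wavelet packet
decomposition of the raw 5 Hz series cannot produce these bands: its
Nyquist frequency is 2.5 Hz, and no depth of dyadic splitting yields
0.0625 Hz intervals. The series is therefore decimated to an effective
1 Hz (zero-phase 8th-order Butterworth anti-alias filter at 0.5 Hz,
then sample picking), after which a depth-3 wavelet packet
decomposition partitions 0–0.5 Hz into exactly the eight printed bands.
This decimation step is the central interpretive decision of the
feature layer: the source protocol states the band scheme but not how
it was reached from 5 Hz data, and the decimation route is the one
reconstruction under which the printed bands coincide with packet
terminal nodes.

Terminal nodes are ordered by natural frequency (the Gray-code
permutation of the recursive low/high order), so node $k$ covers
$[k, k+1) \times 0.0625$ Hz; the mapping is verified in the test suite
by pure mid-band sinusoids for every band. Band energy is the raw sum
of squared coefficients of a terminal node, with no normalization by
length; all downstream use is comparative, so the absolute scale is
immaterial (printed energies from other implementations may differ by
a constant factor).

The wavelet transforms are implemented in the package as periodized
(circular) orthonormal filter banks — db4 by default, with haar, db2,
db8 and sym8 available. Periodization keeps the transform exactly
orthogonal on even lengths, so the eight band energies sum to the
energy of the (truncated) decimated series to machine precision; the
coefficient conventions are pinned against an independent reference
wavelet toolbox in the tests. Series are truncated to a multiple of
$2^3$ samples for the packet transform and padded by edge replication
for denoising.

One consequence of normalization is worth stating plainly: a
normalized series has mean ≈ 0.5, and that DC component lands in
`freq0`, which therefore dominates the other seven bands by an order of
magnitude or more — visible in the published group summaries, where the
task-5 `freq0` energies (~2.5) dwarf all other band energies (~0.1).
Tests of spectral placement for planted bands $k \ge 1$ accordingly
compare against the other oscillatory bands, not against `freq0`.

## Preprocessing

The pipeline is: Hampel outlier removal → linear gap interpolation →
zero-phase low-pass → wavelet denoising → min–max normalization. The
cleaned, un-normalized series is retained for `max`/`min`. Defaults,
with rationale:

* **Hampel filter**: rolling window of 11 samples (2.2 s), flag at 4
  rolling MADs, MAD floored at $10^{-9}$ mV so that locally constant
  windows still flag deviant points. The source protocol names outlier
  removal without a rule; the Hampel filter is the standard robust
  choice for biosignal despiking.
* **Interpolation**: linear across missing runs; leading/trailing gaps
  take the nearest observed value.
* **Low-pass**: 4th-order Butterworth at 0.5 Hz (the top of the band
  scheme), applied forward and backward. The acquisition hardware's
  analog filter is unspecified; this software stage is a stand-in with
  unit DC gain. Filtering uses odd-symmetric edge padding with
  steady-state initial conditions, so constants pass exactly and edges
  carry no start-up transient.
* **Denoising**: db4, depth 4, soft thresholding at the universal
  threshold $\hat\sigma\sqrt{2\log n}$ with $\hat\sigma$ from the
  finest detail level — the common biosignal default, configurable.
* **Normalization**: min–max to $[0,1]$ per task. The published
  normalized-domain group means (≈ 0.42–0.49) sit where min–max places
  them. A constant series maps to all zeros by convention (documented
  and tested).

No stage uses the RNG; the pipeline is deterministic.

## Group comparison

Per feature, a classical one-way ANOVA across the three groups, with
corrected pairwise post hoc p-values. The summary-statistics path
(`anova_from_summary`) computes the identical F from per-group
$(n, \bar x, s)$ alone, which is what allows published group summaries
to be checked without raw data; the two paths agree to $10^{-9}$ on
exact summaries.

The source protocol alternates between Bonferroni and Tamhane's T2
without stating the rule. The package gates on a Brown–Forsythe Levene
test at $\alpha = 0.05$: homogeneous variances → Bonferroni
(pooled-variance pairwise t, p × number of pairs), heterogeneous →
Tamhane's T2 (Welch pairwise t with the conservative Šidák-style
correction $1-(1-p)^m$). Both methods are also directly selectable, and
degenerate Levene inputs fall back to Bonferroni.

No correction is applied across the 108 features by default — the
reproduction mirrors per-feature reporting — but a Benjamini–Hochberg
flag is available. Demographic tests follow the conventional mapping:
ANOVA for three-group quantitative variables, Welch t for two-group
scores, chi-square for sex (Yates correction on 2×2, none for larger
tables), Kruskal–Wallis/Wilcoxon rank tests for ordinal education.

## Discrimination

Four analyses: MDD-vs-HC, BPD-vs-HC, BPD-vs-MDD, and three-class. Each
draws a balanced subsample of 50 participants per group (removing the
77/53/79 imbalance), then evaluates by LOOCV: for every held-out row,
feature standardization (per-column mean/SD) and the classifier are fit
on the remaining rows only. The classifier is an RBF-kernel SVM with
the fixed hyperparameters $C = 1.3$ and $\gamma = 0.0085$; no
hyperparameter search. Standardization before the SVM is this package's
choice — the protocol is silent, but a fixed kernel width on 108
heterogeneous-scale features is otherwise meaningless — and can be
switched off. Multiclass discrimination uses one-vs-one voting, the
conventional SVM default.

Reports compute sensitivity, specificity, accuracy, precision and F1
from the confusion matrix; the three-class report macro-averages
one-vs-rest per-class metrics with equal weight, which reproduces the
published three-class sensitivity/specificity exactly. Binary analyses
also report a rank-based (Mann–Whitney) AUC of the decision scores.
Zero-denominator metrics are reported as 0 with a warning flag rather
than failing. A registry of alternative classifiers (kNN, LDA, logistic
regression, gradient-boosted trees) plugs into the same LOOCV
machinery; only the SVM's behavior is characterized.

Two caveats discovered and documented here rather than hidden:

* **LOOCV permutation nulls are one-sided.** With exactly balanced
  classes, the held-out sample's class is always the training-fold
  minority; when the features carry no label information the SVM can
  collapse to the training majority and score *below* chance (sometimes
  exactly 0). The no-leakage property is therefore asserted as "never
  above chance + 3 SE", not as a two-sided band.
* **Published binary AUCs are not reproducible** without the study's
  decision scores; AUC is exercised on synthetic and oracle inputs
  only. Likewise the published three-class F1 (0.58) matches no
  standard averaging of the published matrix (macro-F1 ≈ 0.587 rounds
  to 0.59) and is not a target.

## Correlation screen

All 108 features against the seven blood markers (cortisol, ACTH, uric
acid, indirect/direct bilirubin, albumin, prealbumin) within one
patient group, Pearson by default with a Spearman switch, pairwise
deletion of missing values, two-tailed p from the t transform.
Significance at p < 0.05 uncorrected mirrors the reproduction target;
a BH flag is available. Healthy controls carry no marker data by
design, and requesting them is an error rather than an empty result.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes —
not electrodermal biophysics. Each recording is

$$x(t) = \text{baseline} + \text{drift} + \textstyle\sum_{k=0}^{7}
  s_k(t) + \varepsilon(t) + \text{spikes},$$

where each band component $s_k$ is white noise band-pass filtered at an
effective 1 Hz rate (4th-order Butterworth per 0.0625 Hz band),
Fourier-upsampled to 5 Hz (spectrum zero-padding, so no interpolation
images above 0.5 Hz), and scaled so its variance equals the profile
weight $w_k$ (mV²); drift is a Gaussian random walk; spikes are
single-sample square deviations placed by a Poisson process — the
simplest artifact the Hampel stage must catch. For any single-band
profile, at least 60% (empirically ≥ 89%) of the non-DC power of the
noise-free signal lies in the intended band, verified against an
independent periodogram.

Defaults are fixed once as the study conditions: group sizes 77/53/79;
six tasks of 120 s (durations are unstated in the protocol, so 120 s is
a configurable convention); 5 Hz; baseline 1 mV; drift step SD
0.02 mV; spike rate 0.02 s⁻¹ at 5 mV; sensor noise SD 0.05 mV. The
default band profiles start from a 1/f-like base (weights
0.8…0.04 mV² from `freq0` to `freq7`) and modulate groups to echo the
published contrast pattern: mid/high-band elevation in MDD (strongest)
and BPD for tasks 1–5, lowest-band elevation in HC for the
emotion-induction task, no group difference for the text task. An
`effect` argument scales these modulations (0 = null cohort).

Metadata are drawn from group-conditional normal models matching the
published demographic and blood-marker summaries; HC scale scores and
blood markers are missing by design. Marker links plant a target
correlation $r$ between a named feature and a marker within each
patient group: after all recordings are generated, the linked feature
is actually extracted through the default preprocessing, z-scored
within the group, and the marker is built as
$\mu + \sigma(r z + \sqrt{1-r^2}\,\epsilon)$ — so the planted
correlation is with the value the pipeline will really compute, and
recovery is testable against the Fisher-z interval for the generated
$n$.

Reproducibility: each participant has an RNG stream derived from
(seed, participant index), so cohorts are byte-identical across runs
and individual participants can be regenerated. What the generator does
*not* emulate — skin conductance response shapes, sweat-gland dynamics,
habituation, electrode drift nonstationarity — bounds what passing
tests show: they validate the pipeline's statistical machinery, not its
adequacy on real electrodermal data.

## Numerical choices and problem sizes

Degenerate inputs have defined behavior throughout: constant series
normalize to zeros; identical group means give F = 0 exactly; MAD-zero
windows use the floored scale; zero-denominator metrics return 0 with a
flag; single-class training folds predict their lone class with a
classed warning (so the smallest legal LOOCV input runs).

The test suite sizes simulations to what the properties need: type-I
error calibration at 2000 replicates (tolerance ±0.015 around 0.05),
planted-shift detection power over 100 replicates on directly simulated
feature matrices at the published group sizes, signal-level generator
checks on cohorts of up to 150 participants with 64 s tasks (the
shortest duration that leaves ≥ 64 samples after decimation), and the
planted-correlation recovery through the full pipeline at $n = 150$
against the Fisher-z 99% interval. The acceptance script additionally
runs a separable 25/25/25 cohort end-to-end through LOOCV and a
150-participant planted-correlation cohort.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_bpd = 25, n_mdd = 25, n_hc = 25,
                    task_durations_s = rep(64, 6), seed = 42)
cohort <- generate_cohort(spec)
fm <- sp_feature_matrix(cohort)
cmp <- compare_all_features(fm)
disc <- run_discriminations(fm, n_per_group = 20, seed = 42)
summary(disc)
screen <- correlate_features_markers(fm, cohort$metadata, "BPD")
```

The published confusion matrices and summary rows ship as fixed inputs
(`reference_confusions()`, `reference_summary_task5_freq0()`); the
metric suite and the F statistic recomputed from them — not looked up —
are what `scripts/acceptance.R` reports.
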