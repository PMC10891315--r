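# sptask — task-state skin potential analysis

`sptask` is an R package for analysing **task-state skin potential
(SP)** recordings — the endogenous electrodermal potential sampled at
5 Hz while participants view emotion-inducing stimulus tasks — and for
asking whether those signals discriminate **bipolar depression (BPD)**,
**major depressive disorder (MDD)** and **healthy controls (HC)**. It
is aimed at psychophysiology and computational psychiatry researchers
who want the complete pipeline from raw voltage series to classifier
metrics as tested, reusable code.

The package implements:

* **Preprocessing** — Hampel outlier removal (rolling median ± *k*·MAD),
  linear gap interpolation, zero-phase Butterworth low-pass at 0.5 Hz,
  wavelet denoising (db4, soft universal threshold), per-task min–max
  normalization.
* **Feature extraction** — the 18-feature set per task: max/min (mV),
  median, mean, variance, RMS, first/second-difference means and SDs
  (normalized domain), and eight wavelet-packet band energies
  `freq0`…`freq7` over the contiguous 0.0625 Hz bands spanning
  0–0.5 Hz, obtained by decimating 5 Hz → 1 Hz and taking the depth-3
  packet terminal nodes in natural-frequency order
  ($E_k = \sum_i c_{k,i}^2$). Six tasks × 18 features give the
  108-column participant matrix.
* **Group comparison** — per-feature one-way ANOVA
  ($F = \mathrm{MS_{between}}/\mathrm{MS_{within}}$), including a
  summary-statistics path that recovers F from per-group
  $(n, \bar x, s)$ alone, with Levene-gated Bonferroni / Tamhane T2
  post hoc pairwise corrections, plus demographic tests (t, chi-square,
  rank-sum).
* **Discrimination** — balanced subsampling (50 per group), RBF-SVM
  with fixed $C = 1.3$, $\gamma = 0.0085$, leave-one-out
  cross-validation with per-fold standardization, confusion matrices,
  sensitivity / specificity / accuracy / precision / F1 (binary and
  macro-averaged three-class), rank-based AUC, and a pluggable
  registry of alternative classifiers (kNN, LDA, logistic, GBDT).
* **Correlation screen** — all features against blood oxidative-stress
  markers (uric acid, bilirubin fractions, albumin, prealbumin,
  cortisol, ACTH) within patient groups.
* **A synthetic cohort generator** — group × task band-energy profiles,
  drift, artifacts, sensor noise and planted feature–marker
  correlations, so every stage is testable without access to clinical
  recordings (which are not publicly deposited).

## Worked example

```r
library(sptask)

spec   <- cohort_spec(n_bpd = 25, n_mdd = 25, n_hc = 25,
                      task_durations_s = rep(64, 6), seed = 42)
cohort <- generate_cohort(spec)
fm     <- sp_feature_matrix(cohort)    # preprocess + extract, all recordings
fm
#> SP feature matrix: 75 participants x 108 features (BPD n=25, HC n=25, MDD n=25)

compare_all_features(fm)
#> Group comparison of 108 features: 7 significant (omnibus p < 0.05)
#>          feature     F       p
#>  task1.diff1_std 7.129 0.00150
#>  task1.diff2_std 6.739 0.00208
#>        task5.var 5.446 0.00627
#>        ...

run_discriminations(fm, n_per_group = 20, seed = 42)
#> Discriminant analyses (svm, 20 per group, LOOCV):
#>   mdd_hc       accuracy 0.50  sensitivity 0.50  specificity 0.50
#>   bpd_hc       accuracy 0.38  sensitivity 0.35  specificity 0.40
#>   bpd_mdd      accuracy 0.57  sensitivity 0.60  specificity 0.55
#>   three_class  accuracy 0.38  sensitivity 0.38  specificity 0.69
```

The default generator plants *subtle* group contrasts (mid/high-band
elevation in patients, lowest-band elevation in controls during
emotion induction), so a small cohort shows a handful of significant
band-energy features and near-chance discrimination — the regime the
method actually operates in; strongly separated profiles drive LOOCV
accuracy above 0.95 (see the test suite). The summary-statistics ANOVA
path works directly on published group summaries:

```r
a <- anova_from_summary(n = c(77, 53, 79),
                        mean = c(2.513, 2.450, 2.773),
                        sd = c(0.616, 0.560, 0.618))
#> F = 5.684, p = 0.0040
```

Here `F = 5.684` says the emotion-induction-task lowest-band energy
differs across the three groups well beyond within-group variability
(p ≈ 0.004), recovered from nine published numbers alone.

A command-line wrapper over the same functions lives in
`inst/scripts/sptask-cli.R` (subcommands `simulate`, `preprocess`,
`features`, `compare`, `classify`, `correlate`, `run-all`; the last
writes a manifest with config, seed and file hashes).

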