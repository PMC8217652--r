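# fearleak

Analysis of **leaked fear** in facial action-unit (AU) time series for
high-stakes deception research.

Leakage theory holds that the fear a liar feels about being caught cannot be
fully suppressed and escapes as brief facial actions. Given per-frame
OpenFace-style output (68 facial landmarks, AU intensities `AUxx_r` ∈ [0,5]
and presences `AUxx_c` ∈ {0,1}) for paired truth/lie clips of the same
speakers, the package asks three questions:

1. **Do fear AUs differ between lying and truth-telling?** Per frame, each
   fear AU (AU1, AU2, AU4, AU5, AU7, AU20, AU26) is scored as
   *presence × intensity*; per-clip means are compared with a paired
   bootstrap *t*-test, Bonferroni-corrected (α/m = 0.05/7 ≈ 0.007), with
   paired effect size d = |t|/√n.
2. **Are fear episodes shorter when lying?** Maximal runs of positive AU
   score are segmented into onset–apex–offset episodes with the additive
   decomposition `(onset→apex) + (apex→offset) = total`; durations convert
   to ms as `frames/rate × 1000`, and episodes at or below 200 ms (6 frames
   at 30 f/s) or 500 ms (15 frames) count as micro/macro expressions.
   Groups are compared with an independent bootstrap *t*-test.
3. **Is the face more asymmetric when lying?** The left/right eyebrow–eye
   distances ld1 (landmarks 20–40) and rd1 (25–43) are compared by
   magnitude-squared **wavelet coherence** (analytic Morlet, ω₀ = 6,
   Torrence–Webster smoothing): R²(s,t) = |S(Wxy/s)|² / (S(|Wx|²/s)·S(|Wy|²/s)),
   summarised per clip as the mean over the cone of influence and tested
   across clips with a two-sample permutation test.

A classification stage (SMOTE oversampling; random forest, k-NN and bagging
with WEKA-style weighted metrics and Cohen's κ) evaluates whether the
seven-AU frame vectors discriminate lie from truth frames, under a
participant-held-out split and leave-one-person-out cross-validation.

The original game-show videos are not distributable, so a **synthetic cohort
generator** reproduces the statistical structure the analysis assumes
(paired truth/lie clips of very unequal length, sparse AU episodes with
shorter decay when lying, left/right distance signals with weaker coupling
when lying), making every stage testable end to end.

## Worked example

```r
library(fearleak)
report <- run_full_analysis(pipeline_config(
  cohort = list(n_participants = 8), n_perm = 1999, n_trees = 30,
  n_train = 6, seed = 42))
print(report)
```

Output (abridged):

```
-- AU20 episode durations --
lie: <duration_summary> 25 episodes
  total: mean 15.88 frames (529 ms), median 14, 95% CI [13.72, 18.04]
  phases: onset-to-apex 9.80, apex-to-offset 6.08 frames
truth: <duration_summary> 412 episodes
  total: mean 20.54 frames (685 ms), median 20, 95% CI [19.83, 21.28]
  phases: onset-to-apex 9.26, apex-to-offset 11.27 frames
apex-to-offset (truth vs lie): <test> means 11.2743 vs 6.0800, t = 8.576,
  95% CI [3.9694, 6.4192], bootstrap p = 0.000, d = 0.922

-- facial symmetry (mean in-cone wavelet coherence) --
means: lie 0.5310, truth 0.8887; <permutation_test> observed diff -0.3577,
  p = 0.0005 (1999 perms), d = 6.685
```

Reading it: the generator injected AU20 episodes whose apex-to-offset decay
averages ~11.3 frames in truth clips and ~7 in lie clips; the segmentation
recovers those means (11.27 / 6.08) and the bootstrap *t*-test flags the
contrast. Lie clips were generated with weaker left–right coupling, and the
coherence summary separates the groups (0.53 vs 0.89, permutation
p = 0.0005). Frame-level classification on these overlapping synthetic AU
distributions lands in the 67–78 % accuracy range with near-zero κ —
accuracy driven largely by the majority class, the same caveat the weighted
metrics expose on real data.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fearleak.R", package="fearleak"))') \
    synth --out cohort_dir --seed 3 --participants 16
... run --config analysis.dcf --seed 1 --out report_dir
... episodes|symmetry|classify --manifest cohort_dir/manifest.csv
```

Configs are flat `key: value` files mirroring `pipeline_config()` arguments.

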