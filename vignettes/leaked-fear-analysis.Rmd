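---
title: "Leaked fear in facial action-unit time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Leaked fear in facial action-unit time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearleak)
```

# The problem and the model

High-stakes lying is hypothesised to produce *leaked* fear: brief,
involuntary facial actions that the liar tries to suppress. The measurable
consequences, given per-frame facial tracking output, are threefold: fear
action units (AUs) may differ in average strength between lying and
truth-telling; fear episodes may be cut short while lying (a shorter
apex-to-offset phase, since suppression acts after the expression has
started); and the two halves of the face may move less symmetrically while
lying. `fearleak` implements all three analyses plus a frame-level
classification stage, on either real OpenFace-dialect CSVs or synthetic
cohorts.

## Fear score

Per frame and AU, the score is presence × intensity (`fear_score()`), i.e.
the detector's 0–5 intensity gated by its binary presence call. Per clip,
the statistic of interest is the arithmetic mean score over all frames
(`clip_mean_aus()`), one number per AU per participant per condition — the
unit of the paired analysis. Two AU sets are supported: the classical
six-AU fear prototype (1, 2, 4, 5, 20, 26) and the seven-AU set with AU7
used by the classifier; the seven-AU set is the default because the
classification stage is the downstream consumer of the feature vector.

## Episode segmentation

`segment_episodes()` takes maximal runs of positive score as episodes. The
apex is the maximum score within the run, resolved to the *earliest* frame
on ties (a deterministic rule; ties occur with plateaued intensities). The
phase convention is the only additive one: onset→apex counts frames
`[onset..apex]` (apex included), apex→offset counts `(apex..offset]`, so
the phases always sum to the total `offset − onset + 1`. This additivity is
what lets the published group means decompose (total ≈ rise + decay). No
gap-merging is applied between runs separated by even a single absent
frame, and no minimum episode length is imposed: duration is defined purely
by presence, and any tolerance would be an unstated extra parameter.
Durations convert to milliseconds as `frames / rate × 1000`, rounding only
at report time. Micro/macro thresholds (defaults 200 ms and 500 ms)
convert to frames by `floor`, giving the conventional 6- and 15-frame
boundaries at 30 f/s.

## Wavelet coherence

The asymmetry metric is the magnitude-squared wavelet coherence of the
left/right eyebrow–eye distance signals (landmarks 20–40 and 25–43,
0-based). The implementation is the standard Torrence–Compo construction:

* analytic Morlet wavelet, ω₀ = 6 (the common default balancing time and
  frequency localisation);
* scales from 2·dt in 12 voices per octave up to n·dt/4;
* cross-spectrum and auto-spectra divided by scale, then smoothed with a
  Gaussian of width equal to the scale in time and a boxcar spanning 0.6
  octave in scale (Torrence–Webster smoothing — without smoothing,
  coherence is identically 1);
* cone of influence at the e-folding time √2·s of the wavelet envelope;
* the per-clip summary is the mean coherence over all in-cone entries,
  pooling scales.

Numerical choices: FFT convolutions are zero-padded to at least twice the
series length so they are linear, not circular; coherence values may
overshoot 1 by floating-point error and are clipped, with a warning if the
overshoot exceeds 1e-6; constant signals are rejected (`DegenerateSignal`)
rather than returning 0/0; frames with `success = 0` are linearly
interpolated before the transform because the CWT needs gap-free input.
Identical signals give coherence 1 exactly (the smoothing cancels), which
the tests assert as the perfect-symmetry limit.

Two choices were genuinely open. The landmark indices are read as 0-based
(the upstream tool's convention); `index_base = 1` is available since a
1-based reading shifts all four points. And the averaging region for the
per-clip scalar is the full in-cone map, all scales pooled — the source
analysis does not state its region; restricting to a scale band would add a
parameter with no stated value.

## Inference

* **Paired comparison** (`paired_bootstrap_t()`): classical paired t and
  95% CI (t-distribution, df = n−1); a two-sided bootstrap p from 1,000
  resamples of the paired differences (percentile method: twice the
  smaller tail around zero, capped at 1); paired effect size d = |t|/√n,
  the convention that reproduces published effect-size columns.
* **Independent comparison** (`independent_bootstrap_t()`): Welch t,
  group-wise bootstrap resampling, pooled-SD Cohen's d.
* **Bonferroni**: α/m, reported at 3 decimals (0.05/7 → 0.007).
* **Permutation test** (`permutation_test()`): difference of means,
  10,000 uniform label permutations by default, add-one two-sided p
  `(#{|perm| ≥ |obs|} + 1)/(n_perm + 1)` — never exactly zero, and valid
  (P(p ≤ α) ≤ α under the null, which the calibration test checks
  empirically). Groups with all values identical raise
  `DegenerateGroups`.

The exact bootstrap-p definition used in the original analysis is unknown;
the percentile method was chosen as the simplest procedure consistent with
"bootstrap with 1,000 iterations", and published p-values are therefore
matched qualitatively (significance at the 0.007 threshold), not
digit-for-digit.

## Classification

Frame-level seven-AU vectors, labels lie/truth, participant ids as groups.
SMOTE (`smote_oversample()`) upsamples the minority class to parity:
each synthetic row is `parent + U(0,1)·(neighbour − parent)` with the
neighbour drawn from the parent's 5 nearest minority neighbours. Learners
mirror the cited tool's defaults where the source states none: random
forest with 100 CART trees and mtry = ⌊log₂p + 1⌋, k-NN with k = 1 (the
IBk default), bagging with 10 full trees. The CART base learner (Gini,
exhaustive splits) is compiled code because no tree package is available
in the target environment. Metrics follow the WEKA conventions: per-class
TP/FP rate, precision, recall, F-measure and PRC area (average precision),
weighted by class frequency — which makes weighted TP rate equal
accuracy/100 — plus Cohen's κ. Undefined ratios contribute 0.

Two evaluation modes address the frame-autocorrelation leakage risk:
`frame_cv(mode = "paper")` applies SMOTE to the whole training pool before
frame-level 10-fold CV (faithful to the original pipeline), while
`mode = "leak_safe"` resamples inside each training fold. The
participant-held-out split (`train_eval_split()`) and
`leave_one_person_out()` never mix a participant across train and test.

# The synthetic cohort: what it emulates, and what it does not

`cohort_spec()` defaults state the emulated world: 16 participants, one
merged truth clip (mean 105.5 s) and one lie clip (mean 7.8 s) each at
30 f/s; AU episodes at 24 per minute per AU (derived once from the
published episode counts: 675 episodes in ~28 truth-minutes ≈ 24/min);
gamma-distributed phase durations (positive and right-skewed, matching the
long-tailed published violin plots) with decay means 11.35 (truth) and
6.98 (lie) frames and a shared rise mean of 9.42 frames; episode placement
uniform with non-overlap rejection; peak intensities 0.5 + 4.5·Beta(2,2).
Distance signals are baseline 30 px + 3 px of Gaussian-smoothed noise; the
right signal is the left delayed by 1 frame (truth) or 3 frames (lie) and
mixed with independent noise at weight 0.25 (truth) or 0.55 (lie). The
lag/noise defaults were fixed a priori to produce a coherence gap in the
published direction; the published dispersions are unknown, so synthetic
dispersions (gamma shape 4, clip-length shape 4) are free parameters and
must not be read as estimates of the original data.

The four signal landmarks are embedded exactly (the paired landmark sits
directly below at distance ld1/rd1); all other landmarks are a fixed
template face plus 0.05 px jitter. Consequently a green pipeline run
establishes that the *machinery* recovers planted structure — episode
means within sampling error, coherence ordering, group labels — not that
real faces behave this way: there is no head pose, no correlated AU
co-activation, no detector noise or failed frames, and the AU channels of
the two classes differ only through episode dynamics, which is why
synthetic frame-level classification shows modest accuracy with near-zero
κ rather than the published 86%.

# Degenerate inputs and error surface

Errors are classed conditions (`MissingColumn`, `MalformedRow`,
`EmptyTable`, `MixedIdentity`, `OutOfBounds`, `TooShort`,
`LengthMismatch`, `EmptyMask`, `TooFewMinority`, `ParticipantOverlap`,
`SingleParticipant`, …) so callers can branch on them. The reader never
fills missing AU columns silently; header whitespace is trimmed because
the upstream dialect pads header names. Frames with `success = 0` are
*kept* by default everywhere (the source analysis mentions no exclusion);
`drop_failed`/interpolation flags expose the alternative.

# Known limitations

* Published headline numbers that depend on the unavailable videos
  (accuracies, coherence means, episode counts) are treated as qualitative
  structure only.
* The independent-samples effect sizes printed in the source (0.276,
  0.347, 1.3144) cannot be reconciled with any standard formula without
  the raw dispersions; the package reports pooled-SD d.
* Coherence significance contours (AR(1) surrogate Monte-Carlo) are out of
  scope; the source reports none.
* The CART learner is axis-aligned with exhaustive splits; it is not a
  drop-in reimplementation of WEKA's REPTree/RandomTree, and printed
  accuracies are not expected to reproduce.
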