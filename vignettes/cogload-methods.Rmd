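---
title: "Methods and design notes for cogload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cogload}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cogload` studies how a subject's task skill shapes the separability of
rest and task EEG. This vignette records the model, the numerical choices,
and the places where the design was genuinely open — in enough detail that
a maintainer can judge what a green test does and does not establish.

## Empirical mode decomposition

Each channel is decomposed by classic sifting. One candidate mode is
refined by subtracting the mean of its upper and lower envelopes (natural
cubic splines through the local maxima/minima) until the normalized
squared change between successive iterates,
`SD = sum((s2 - s1)^2) / sum(s1^2)`, falls below `q`. Choices a user
should know about:

* **SD-criterion form.** The defining ratio is ambiguous between a
  point-wise ratio summed and a ratio of sums. We use the ratio of sums
  (global normalization): the point-wise form divides by `s1(t)^2`, which
  passes through zero at every zero-crossing of the iterate and makes the
  statistic numerically unstable. The global form is also what mainstream
  EMD implementations compute.
* **Threshold** `q = 0.25`, the midpoint of the conventional 0.2–0.3
  range; configurable everywhere.
* **Envelope boundaries.** Splines through extrema swing wildly at the
  ends. We mirror the two nearest extrema across each end before fitting —
  standard anti-edge-swing practice. Variant implementations differ
  exactly here, which is why the cross-implementation test demands only
  correlation > 0.9 on the first three modes.
* **Termination.** A safety cap of 100 sifting iterations per mode
  guarantees termination; in practice 1–5 iterations suffice at
  `q = 0.25`. Signals whose residual has fewer than two maxima or two
  minima stop decomposing early; downstream feature extraction then raises
  an "insufficient modes" error naming the channel rather than padding.
* **Plateaus** in `find_extrema` contribute one extremum at the plateau
  centre, so quantized (EDF round-tripped) signals behave like their
  continuous originals.

Six modes are extracted. The first five carry features; the sixth exists
only as the adjacent-band partner of the fifth (see below). Whole segments
are decomposed at once — the analysis produces exactly one 570-value
vector per subject-condition, not per sub-epoch.

## Features

For mode `D` with partner mode `E` (the next, lower-frequency mode):
mean, SD, skewness, kurtosis, RMS and `R_a = sum(|D|)/sum(|E|)`. All
moment divisors are `1/n` (population form), which makes
`RMS^2 = mean^2 + SD^2` an exact identity — the test suite asserts it to
1e-10 on every extracted mode, pinning the convention. Cohort *score*
statistics deliberately use the `n-1` sample SD instead: that is the only
convention that reproduces the published 3.37 / 7.46 from the published
36-score column, as the acceptance test verifies.

The layout is channel-major over the fixed montage (Fp1, Fp2, F3, F4, Fz,
F7, F8, C3, C4, Cz, P3, P4, Pz, O1, O2, T3, T4, T5, T6), then mode 1–5,
then the six features: 19 × 5 × 6 = 570 values. The montage vector is the
single source of truth shared by the EDF reader, the feature layout and
the topography.

## Classification

Soft-margin SVM with standardized predictors and kernel
`(x·z/γ + 1)^order`, `order = 4` by default and `γ` = number of retained
features — the common semantics of "standardized predictor + polynomial
kernel" toolboxes. The dual QP is solved exactly (`quadprog`) with a tiny
ridge (1e-8 of the diagonal scale) for strict positive definiteness, so
training is deterministic. Open choices, decided once:

* `C = 1` (unstated in the source analysis).
* Exact-zero decision values resolve to `class_1` (rest): conservative
  toward the null state.
* Zero-variance training features are excluded from standardization and
  kernel; prediction ignores the same columns.
* The all-subject evaluation design (E2) never states its training set in
  the source; we train on the first 20 subjects and predict all 36 —
  consistent with a soft-margin model misclassifying some early subjects.
  E2 and E5 are deliberately non-disjoint (flagged on the design object);
  E1, E3, E4 keep both condition vectors of each subject strictly on one
  side of the split, and the tests assert it.
* "First N subjects" means ascending subject-ID order. The Average_GOOD
  split (E4) is constructed from its rule — the 10 lowest-X GOOD subjects
  train, the other 16 test — not from the published table rows, whose
  ID/score pairing is internally inconsistent.
* Baselines: LDA (`MASS`), 1-nearest-neighbour (`FNN`; k = 1 chosen as
  the conventional parameter-free default), and — because no decision-tree
  or naive-Bayes library exists in the supported environment — a small
  depth-capped Gini CART and a Gaussian naive Bayes implemented in the
  package with standard defaults.

## Evaluation

A prediction table has one row per test subject with the predicted labels
of both segments. Both-class accuracy is the fraction of subjects with
rest *and* task correct; class-wise accuracies count each segment;
overall accuracy is correct segments over 2n. Reversed /
both-as-class_1 / both-as-class_2 counts mirror the published comment
column. Three published footer values (80.8%, 71.4%, 66.88%) are not
reproducible from their own printed per-subject rows (direct counts:
80.56%, 69.44%, 65.38%); `reproduce_tables()` reports the recomputed
definition and flags the discrepancy rather than chasing the printed
numbers.

## Synthetic cohort: what it emulates, and what not

The generator is a *stated world*, not a tuning knob. Defaults: 10 + 26
subjects; 500 Hz; 19 channels; scores from truncated normals
(mean 6.2, SD 3.37 and mean 21.99, SD 7.46; truncated to [1, 40], rounded
to 2 decimals as the published table prints them); group labels by the
threshold rule X ≤ 10. Each channel is pink noise (spectral slope −1,
SD 5 µV) plus a 10 Hz alpha component (8 µV base, occipital-dominant,
factor 0.75 during task — mild task-related alpha suppression) and a 6 Hz
theta component (5 µV base, frontal/central/parietal-dominant) whose task
amplitude is scaled by `1 + effect·(1 − skill)`, with `skill` mapped
linearly from the score range 1–30. `effect_bad = 1` by default;
`effect_good = 0.1`, a free choice (the source quantifies the high-skill
effect only as far smaller than the low-skill one). Segment lengths
default to 30 s (not the real 180/60 s) for test speed; full lengths are
one config field away. Expected channel power has the closed form
`noise_sd² + Σ amp²/2`, exposed as `expected_channel_power()` and used as
the analytic oracle in tests.

The generator does **not** emulate eye blinks, EMG bursts, ERPs,
non-stationarity, inter-channel correlation, or any connectivity
structure. A green synthetic test therefore establishes that the pipeline
recovers the *stated* group-contrast regime (direction-only), not that
the real recordings would reproduce any particular accuracy. The
published real-data numbers (68.75%, 50%, 93.06%, …) require the real
recordings, which are not distributed; `run_real_designs()` exists for
users who have them. Test and acceptance runs use further-scaled-down
cohorts (4+6 to 5+8 subjects, 6–20 s segments) purely for runtime; the
regime parameters themselves (large `effect_bad`, near-zero
`effect_good`) are fixed before measurement and asserted by sign tests
over ≥ 20 seeded cohorts.

## Topography and image similarity

Per-channel mean squared amplitude (µV²) after per-subject normalization:
both conditions of a subject are divided by the channel SD over the
*concatenated* rest + task samples. The normalization method is unstated
in the source; the shared scale is the only simple choice that removes
inter-subject amplitude differences while preserving the rest/task power
ratio the figures display (per-condition standardization would erase it).

Topographies are exact thin-plate-spline interpolations (affine part plus
`r² log r` terms) of the 19 values over a 64×64 grid on the unit head
disc, masked outside the circle, with electrodes at the standard schematic
10/20 projection (bundled CSV). No extrapolation beyond the head circle.

The image-similarity index is implemented as mean SSIM with a sliding
7×7 uniform window and standard constants (C1 = 0.01², C2 = 0.03²) on
min–max-rescaled fields; window statistics use only unmasked cells. The
source never defines its index, and whether it was computed on rendered
colour images or raw fields is unknowable; absolute values are therefore
not comparable and only the group *ordering* (GOOD rest/task maps more
similar than BAD) is asserted, as a stochastic direction-only test.

## EDF input/output

No EDF library exists in the supported R or Python environment, so the
package implements the format directly: 256-byte fixed header, 256 bytes
of per-signal fields, little-endian 16-bit data records mapped linearly
between the declared digital (−32768..32767) and physical ranges.
Physical units are assumed µV. Round-trip error is bounded by half a
quantization step (range/65535 per channel), which the tests assert.
Channel matching trims an optional "EEG" prefix and is case-insensitive;
the modern temporal aliases (T7→T3 etc.) apply only on explicit opt-in.
EDF+ annotations and BIDS directory validation are out of scope.

## Known limitations

* EMD has no uniqueness guarantee; different boundary treatments yield
  slightly different modes, which is why cross-implementation agreement is
  asserted loosely (r > 0.9, first three modes).
* The SVM QP is dense (fine for tens of training vectors per design; not
  meant for thousands).
* The synthetic world is stationary and sinusoidal-plus-pink-noise;
  effect sizes in µV are plausible but not fitted to the real recordings.
* Absolute SSIM values depend on grid resolution and window size;
  compare only within a fixed configuration.
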