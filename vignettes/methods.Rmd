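---
title: "Classifying walking independence from eight body-worn IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying walking independence from eight body-worn IMUs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imugait)
```

## The problem

Physiotherapists in acute-care wards decide when a hospitalized patient may
switch from a walker to a cane or unaided walking. The decision weighs not
only speed on the 10-m walk test (10MWT) and Timed Up-and-Go (TUG) but how
the patient moves. `imugait` implements a pipeline that makes that judgment
from data: eight inertial measurement units (chest, lower back, both wrists,
both thighs, both ankles), each recording 3-axis acceleration and 3-axis
angular velocity at 120 Hz, feed a Transformer classifier that labels each
left gait cycle as *walking acquired* (WA) or *not acquired* (NA, the
positive class — the clinically costly miss is the patient who still needs
the walker).

Because clinical recordings of this kind are not publicly available, the
package ships a synthetic cohort generator with ground-truth gait events so
that the entire pipeline is exercised, tested and benchmarked end to end on
data whose truth is known.

## Pipeline

1. **High-pass filtering.** Acceleration channels are filtered at 1 Hz to
   remove gravity; angular velocity is left untouched. The filter
   realization — unavoidably a design choice — is a 4th-order Butterworth
   applied forward and backward (zero phase), the standard choice in gait
   analysis because it preserves event timing. There is no DSP dependency in
   the target stack, so the design (analog prototype, lowpass-to-highpass
   transform, bilinear transform) and the zero-phase filter (odd-reflection
   padding, steady-state initial conditions) are implemented in the package
   and were cross-checked against an independent reference implementation
   during development.

2. **Initial contacts (ICs).** For each ankle, the combined acceleration
   $a = \sqrt{a_x^2 + a_y^2 + a_z^2}$ is differenced over one sample and its
   periodic peaks mark initial contacts. "Periodic peak" needs a concrete
   criterion; the package uses four scale-free rules, all configurable:
   a minimum separation of 0.6 s (hospital patients walk slowly; per-side
   cycles run well above 1 s); a prominence floor of 0.3 times the robust SD
   (1.4826·MAD) of the differenced series; a relative-height floor of 0.4
   times a reference height, taken as the median of the five tallest
   candidates (robust both to a single artifact spike and to crowds of
   small noise candidates from still periods — a plain candidate quantile
   fails in recordings that are mostly non-walking, such as the TUG); and a
   periodicity cleanup that, whenever two accepted peaks lie closer than
   0.6 times the median inter-peak gap, discards the smaller of the pair.
   The last two rules are what make the criterion *periodic*: the
   once-per-cycle contact transient towers over within-cycle maxima, and
   the rhythm constraint adapts to each subject's cadence instead of a
   fixed time constant. All references are relative, so doubling the signal
   amplitude leaves the detected indices identical — a tested property.

3. **TUG sub-phases.** Sit-to-stand and stand-to-sit anchor at the global
   maximum and minimum of the lumbar pitch angular velocity; the two turns
   anchor at the two largest absolute yaw values between them. Each phase
   extends over the contiguous region around its anchor where the channel,
   normalized by its own maximum absolute value within the trial, stays at
   or above 0.1 — the threshold is dimensionless because the traces it was
   defined on are normalized. The two walking phases are derived: end of
   sit-to-stand to first-turn start, and first-turn end to second-turn
   start. Only these walking phases contribute gait cycles; 10MWT trials
   contribute everything between the second and the second-to-last detected
   contact (first and last cycle excluded).

4. **Left gait cycles.** One window per consecutive pair of left-ankle ICs
   inside a walking phase, carrying all 48 channels, half-open
   `[IC_i, IC_{i+1})`, 1-based indices throughout (the R convention; the
   arithmetic — length = end − start, adjacency of phases — is unchanged).

5. **Normalization.** For each of the six modality-axis channel groups, the
   denominator is the maximum absolute value across all 8 sensors and all
   samples of the subject-trial; every value maps to
   $x / M / 2 + 0.5 \in [0, 1]$ with the baseline 0 at exactly 0.5. Within
   each trial and group the bound that is attained (min 0 or max 1) depends
   on the sign of the extreme value — an invariant the tests assert. The
   scope (per subject-trial, pooled over sensors) is what makes inter-sensor
   amplitude ratios informative and makes the whole pipeline unit-free.

6. **Padding.** Windows are padded to a common length with the baseline
   constant 0.5. The reference cohort's longest cycle was 276 samples at
   120 Hz; `length_max` is a parameter because it is a property of a cohort,
   not a universal constant — on synthetic cohorts the observed maximum is
   used. Windows longer than the target are an error, never truncated.

7. **Augmentation, balancing, folds.** Training data are expanded five-fold
   with uniform noise on ±0.1 added to every value (originals kept; noisy
   values clipped back to [0, 1]). Class balance is restored by seeded
   undersampling of the majority label. Evaluation is leave-one-subject-out:
   the held-out subject's unaugmented cycles are the test set; the remaining
   pool is split 90/10 into train/validation; augmentation happens *after*
   the split, on the training portion only. The reference description
   augments before splitting, which risks placing noisy copies of one
   original on both sides of a split; the leakage-free order is the default
   here. Sensor ablation replaces the six channels of each excluded site
   with the constant 0.5 in train, validation and test alike.

## The classifier

A Transformer encoder matching the reference architecture: learned linear
embedding 48 → 48 (the layer's table maps 48 to 48, leaving identity vs
learned open; a learned map is the default and configurable), fixed
sinusoidal positional encoding, five post-norm blocks (multi-head
self-attention and feed-forward, each wrapped in residual + LayerNorm),
flattening over time and model dimensions — 276 × 48 = 13248 features at the
reference shape — and a fully connected softmax classifier with two outputs.
Heads (4), feed-forward width (128) and dropout (0.1) are free parameters of
this implementation, chosen small enough to train on one CPU while dividing
the model width. Training minimizes cross-entropy with Adam; the reference
schedule is 130 epochs, batch 64, learning rate 1e-5, no scheduler, no early
stopping, final-epoch model kept.

There is no deep-learning runtime in the target stack, so forward and
backward passes are written from scratch (RcppArmadillo). The batch is
processed as one stacked matrix so projections, feed-forward and LayerNorm
are single BLAS calls. Correctness of the backward pass is established by a
numerical-differentiation test (worst relative error ~1e-7 on a small
configuration); one pleasant analytic check falls out for free: the
attention *key* bias shifts every softmax row by a constant, so its gradient
is exactly zero, and the test asserts it.

Two training-dynamics notes. First, post-norm encoders pass through an
initial plateau before the loss falls; at the reference schedule (tiny rate,
many epochs) this resolves by itself, but short runs at higher rates benefit
from a brief linear learning-rate warm-up, available as
`train_config(warmup_steps = )` and off by default. Second, dropout masks
are drawn from a fast xorshift generator seeded from R's RNG, so
`set.seed()` reproduces a training run bit for bit.

## The synthetic cohort: what it emulates and what it does not

Walking is modeled per channel as the sum of the first four harmonics of the
subject's gait fundamental, with site-specific amplitudes (ankle-dominant
vertical acceleration, wrist channels scaled by arm swing), a half-cycle
phase shift between body sides, a sharp ~2 g half-sine transient on the
ankle at each initial contact, gravity on the vertical axes, and Gaussian
sensor noise. TUG trials add raised-cosine lumbar bursts — positive pitch
(sit-to-stand, 1.5 s), two yaw bursts (turns, 2 s), negative pitch
(stand-to-sit) — whose 10%-of-peak crossings define the ground-truth phase
boundaries.

The two groups differ in cycle duration (WA 1.10 ± 0.08 s vs NA
1.45 ± 0.12 s between subjects, mirroring the roughly 0.85 vs 0.61 m/s group
speeds reported for slow hospitalized cohorts), overall amplitude (×0.7 for
NA), arm swing (×0.5) and cycle-to-cycle variability (0.020 vs 0.035 s). A
small fraction of subjects (default 5%) lack TUG recordings, as happens in
practice; such subjects contribute 10MWT cycles and are never dropped.

One generator decision deserves emphasis. An early version drew all
harmonic phases independently per subject. That gave every subject a unique
spectral fingerprint, the classifier memorized the training subjects, and
leave-one-subject-out accuracy collapsed even though the classes were
cleanly separated — a failure of the *generator's* realism, not of the
pipeline: real gait shares its inter-channel phase structure across people,
because biomechanics dictates when each segment accelerates within a cycle.
Phases are therefore a fixed common pattern plus a small per-subject jitter
(SD 0.3 rad), and per-channel amplitudes get mild individual variation
(log-normal, SD 0.10).

What a green end-to-end test establishes: the pipeline's plumbing is sound —
events are recovered, no subject leaks across folds, the model can learn
class structure that generalizes to unseen subjects. What it does not
establish: clinical performance. The synthetic classes are a stated stand-in
with a deliberately clear gap; real patients differ in ways (pathological
asymmetries, aids, sensor placement error) the generator does not attempt.

## Numerical and scale choices

- **Tolerances.** IC timing is asserted to a median error below 25 ms
  (3 samples at 120 Hz); TUG boundaries to ±0.1 s; metric identities
  (accuracy as prevalence-weighted sensitivity/specificity) to 1e-12.
- **Degenerate inputs.** Constant signals yield zero contacts; all-zero
  channel groups make the normalization denominator zero and are an error;
  windows longer than `length_max` are an error; metrics with zero
  denominators are `NA`, never silently 0. Prediction ties break toward the
  first class deterministically.
- **Seeds.** Per-subject generator seeds are `master + 1000·rank`; per-fold
  seeds are `master + fold index`; all randomness (undersampling, splits,
  augmentation noise, initialization, shuffling, dropout) flows from them.
- **Test scale.** The heavy end-to-end check keeps the 12-subject (7 WA /
  5 NA) cohort and default class gap but runs at 30 Hz, one trial per test
  type, 8 epochs (batch 32, rate 1e-3, 60-step warm-up) and two master
  seeds, to fit a single-CPU budget; thresholds are not relaxed. The
  gait-band content of the generator (≤ ~4 Hz) is far below the 15 Hz
  Nyquist at that rate. Structural checks (276-sample padding, 48 channels,
  13248-wide flatten, five-fold augmentation, one model per subject) run at
  the full reference shape.

## Known limitations

- The generator is a signal-level emulation, not a musculoskeletal model;
  no orientation estimation or sensor fusion is attempted.
- Right-cycle analysis is supported (`side = "right"`) but not exercised by
  the headline pipeline.
- Regional (per-sensor) normalization, discussed in the source work as a
  possible variant, is not implemented.
- Whether angular velocity should also be high-pass filtered is left as in
  the reference description: only acceleration is filtered.
- The train/test "ratio of 0.1" is read as the validation split within each
  LOOCV training pool; the alternative reading (a separate evaluation
  split) is not implemented.
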