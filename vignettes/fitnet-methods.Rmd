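---
title: "Estimating finger kinematics from surface EMG: models, data and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating finger kinematics from surface EMG: models, data and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface electromyography (sEMG) records the electrical activity of
contracting muscle from skin electrodes. In continuous myoelectric control,
a regressor maps a short window of multichannel sEMG to the current hand
posture — here, 10 finger-joint angles (the metacarpophalangeal and
proximal-interphalangeal flexions that do most of the work in grasping) from
12 forearm electrodes sampled at 2 kHz, the configuration of the Ninapro DB2
benchmark. `fitnet` implements this pipeline end to end: feature extraction,
leakage-safe dataset construction, four sequence-regression models trained
by backpropagation, the PCC / NRMSE / R^2 evaluation protocol, and
nonparametric significance analysis.

## The FIT regressor

The core model, FIT (fusion inception-transformer), interleaves
convolutional local feature extraction with transformer-style global
sequence modeling. An input window of `L` feature frames by 12 channels
passes through:

1. **Stem**: a kernel-1 convolution lifting 12 electrode channels to
   `C = 32` feature channels.
2. **Inception block** (per stage):
   - *Efficient downsampling (HED)*: two parallel branches — a kernel-2,
     stride-2 convolution (`C -> C`) and a kernel-2 average pooling —
     concatenated on the channel axis, so the sequence length halves while
     the width doubles (`L x C -> L/2 x 2C`), followed by batch
     normalization.
   - *Multi-scale convolution (MSC)*: the `2C` channels are split into four
     equal groups; groups 1–3 pass through same-length convolutions with
     kernels 3, 5 and 7, group 4 is an identity path that preserves the
     incoming features; the concatenation is passed through an ELU
     activation and batch normalization.
3. **Transformer block** (per stage): two pre-layer-norm residual
   sublayers, `x + MHA(LN(x))` followed by `x + FFN(LN(x))`. The
   multi-head attention uses head counts 4 (stage 1) and 6 (stage 2); the
   softmax logits are scaled by `1/sqrt(C_b)` with `C_b` the full block
   width, not the per-head width — the block's stated convention — and a
   `scale_mode` switch restores the conventional per-head scaling. With
   `C_b = 128` and 6 heads the per-head width is `floor(128/6) = 21`; the
   concatenated width 126 is mapped back to 128 by the output projection.
   The feed-forward sublayer expands by 4x with a GELU nonlinearity.
4. **Readout**: global average pooling over the remaining frames, then a
   linear map to the 10 joint angles. (A last-frame readout is available
   via `readout = "last"`.)

With the default `L = 200` the internal shapes run
`200x32 -> 100x64 -> 50x128 -> 10`. Dropout is not used anywhere.

### Baselines

* **LSTM** — two stacked layers of 128 hidden units; the last hidden state
  feeds a linear readout.
* **TCN** — five dilated causal residual levels, kernel 3, dilations
  1/2/4/8/16, channels 32/64/64/64/128, two convolutions per level with a
  kernel-1 shortcut where widths differ; readout from the last time step.
  The receptive field is `1 + 2(k-1)(1+2+4+8+16) = 125` frames, verified by
  perturbation in the test suite.
* **BERT-style encoder** — linear embedding to 128 dimensions, a learned
  class token and learned positional embeddings, two pre-layer-norm encoder
  blocks with 8 heads, readout from the class token state.

All forward and backward passes are implemented in this package
(RcppArmadillo kernels for convolution, attention and the LSTM recurrence;
analytic gradients are verified against central finite differences in the
test suite at tolerance 1e-4 on every layer type and on all four assembled
models). Training uses Adam (beta 0.9/0.999), mean-squared error on
z-scored targets, batch size 64, learning rate 1e-3 halved-schedule: after
half the epochs it drops to 1e-4. The LSTM family trains for twice the
epochs of the others, reflecting its slower convergence; the fast profile
extends the same doubling to the TCN, the only family without internal
normalization, whose loss is still falling steeply when a 15-epoch
schedule halves the learning rate. Every run is a
pure function of `(model seed, training seed)`: weight initialization, data
shuffling and batch-norm statistics are fully reproducible, and identical
reruns produce bit-identical evaluation reports on the same platform.

## Preprocessing

* **RMS envelope**: per channel, `sqrt(mean(x^2))` over a 100 ms window
  (`N = 200` samples at 2 kHz) sliding by `rms_step_ms` (0.5 ms by
  default). Frames are time-stamped at the window's last raw sample, and
  angles are aligned to that sample.
* **Unit scaling**: each channel is divided by its *training-set* maximum;
  held-out data are clipped to `[0, 1]`. The companding step requires
  `|x| <= 1` and the scaling convention is the package's choice, fitted on
  training data only.
* **Mu-law companding**: `F(x) = sign(x) ln(1 + mu|x|) / ln(1 + mu)` with
  `mu = 255` (the telephony standard; the parameter is exposed). It is
  strictly monotone and odd, fixes 0 and 1, and expands the small
  amplitudes where most of the envelope's information lives.
* **Windows**: model inputs are `L` consecutive frames; the target is the
  angle vector at the window's last frame, applied uniformly to all four
  models for comparability. Windows never cross trial or split boundaries.
* **Targets**: z-scored per joint on training data (scale floored at 1e-6);
  all reported metrics are computed after inverting back to degrees.

### Splits, folds, and leakage

Two leakage-safe 7:3 splits are provided; both assign *contiguous* blocks
of time to each side, never shuffled windows.

* **By repetition** (`split_by_repetition()`, the default used by the
  experiment runners): for each movement, the first `round(0.7 * n_reps)`
  repetitions — whole trials with their trailing rest — train, the
  remaining repetitions test. This is the standard protocol for
  repeated-trial sEMG datasets and the only split under which every
  movement phase (onset, hold, release, rest) occurs on both sides. The
  alternative below was evaluated first and is kept for completeness, but
  with stereotyped trials it holds out the release phase *entirely* — a
  sequence model then faces temporal patterns absent from training and its
  held-out error says more about extrapolation than about the learned
  EMG-to-angle mapping.
* **Temporal within phase segments** (`split_train_test()`): each maximal
  run of constant (stimulus, repetition) — a movement execution or a rest
  period — contributes its first 70% of frames to training and the
  remainder to test.

The temporal k-fold protocol (`make_folds()`) cuts each phase segment into
`k` contiguous pieces; fold 1 covers movement onset, middle folds the hold
phase, late folds the release. In all protocols a guard strip is removed
from the head of every piece that follows a boundary: an RMS frame's window
spans `rms_window` raw samples, so the first
`ceiling((window - step)/step)` frames after a cut still overlap raw
samples seen by the other side. With these guards the raw-sample index sets
underlying training and test windows are provably disjoint, which the test
suite checks exhaustively on reduced data.

## The synthetic data generator

Real Ninapro DB2 recordings require an external download, so the package
ships a generator that reproduces the *structure* of such a session and a
known, recoverable EMG-to-angle mapping:

* **Trial layout** — `n_movements = 6` classes x `n_reps = 6` repetitions,
  each 5 s of movement followed by 3 s of rest at 2 kHz; stimulus and
  repetition labels follow the convention that 0 marks rest. A default
  recording is exactly `6 * 6 * 8 * 2000 = 576,000` samples with
  `move_dur * fs` samples per (movement, repetition) pair.
* **Latent drive** — each movement activates a sparse nonnegative
  combination of `n_synergies = 4` latent synergies with a smooth
  rise–plateau–fall profile (raised-cosine ramps over 20% of the trial).
  On top of this, a low-amplitude tonic component (smooth, band-limited
  stochastic "muscle tone", default 15% of the movement peak) is present
  throughout. The tonic term matters: a resting hand is never perfectly
  still, and without it the rest phase would have constant angles, making
  any rest-heavy evaluation segment statistically degenerate (PCC against
  a constant is undefined).
* **Mixing** — fixed, seeded nonnegative matrices map synergies to the 12
  EMG channels and to the 10 joints. Different subject ids redraw the
  mixing matrices but share the trial structure.
* **EMG** — a zero-mean band-limited (20–450 Hz) Gaussian carrier is
  amplitude-modulated by `1 + g * activation`, with `g` set by `snr_db`
  (20 dB by default; the modulation is 10x the unit noise floor).
  Multiplicative amplitude modulation of band-limited noise is the
  standard phenomenological sEMG surrogate.
* **Angles** — the joint-space drive is low-pass filtered at 4 Hz
  (second-order, zero-phase), emulating the bandwidth of glove kinematics
  natively sampled at 20 Hz, then mapped affinely into each joint's range
  (`[0, 90]` degrees by default).

Generation is a pure function of `(config, subject_id)`. What the generator
does *not* emulate: motor-unit physiology, electrode shift, fatigue,
crosstalk structure, or the idiosyncratic per-subject kinematics of real
hands. Passing the learnability checks below therefore demonstrates that
the pipeline and models can recover a plausible envelope-to-kinematics
mapping under realistic noise — not that the same accuracy would be reached
on real DB2 subjects.

## Problem sizes for desk-scale runs

The experiments in the test suite and in `scripts/acceptance.R` use the
package's fast profile (`fast_profile()`): envelope hop 20 ms (a 50 Hz
feature rate), window length `L = 64` frames (1.28 s of context), training
window stride 10 frames, evaluation stride 1, and 15 training epochs (30
for the LSTM and TCN families). These sizes were chosen once so that training all four
models on a full synthetic subject (6 movements x 6 repetitions) completes
in minutes on a single CPU core; the architectures themselves are
unchanged. The 50 Hz envelope retains all kinematic information (the angle
bandwidth is 4 Hz), a 1.28 s window is also short enough that held-out
windows exist under the stricter temporal split, and `L = 64` satisfies
the divisibility the two downsampling stages require. The full-rate
defaults (0.5 ms hop, `L = 200`) remain the package defaults for
real-data work.

## Evaluation and statistics

Per joint over the concatenated test-window predictions:
Pearson correlation (PCC), R^2 in the standard residual form
`1 - SS_res/SS_tot`, RMSE in degrees, and NRMSE = RMSE divided by the range
of the *true* angles of that evaluation segment — the only normalization
under which NRMSE is confined to roughly `[0, 1]`. (A variance-ratio
variant of R^2, `1 - SS_est/SS_tot`, is available behind a flag for
comparison with reports that print that form; it is not the coefficient of
determination and is not used in any aggregate.) Undefined cells — a
constant true trace, a zero-variance prediction — are reported as `NA` with
a warning and excluded from aggregates.

Model comparison follows the repeated-measures nonparametric protocol:
a Friedman omnibus test over the paired score matrix (subjects x models, or
joints x models when only one subject is available), then pairwise Wilcoxon
signed-rank tests at alpha = 0.05. The Wilcoxon p-value is exact for up to
25 pairs — computed from the full distribution of the signed-rank sum over
all 2^m sign assignments via a polynomial-count dynamic program that
handles average ranks for ties — so 10 paired units with a consistent sign
give the familiar two-sided p = 2/1024 = 0.00195; beyond 25 pairs a
tie-corrected normal approximation with continuity correction is used.
Zero differences are dropped with a warning.

## Numerical and design choices worth knowing

* Batch normalization uses biased batch variance, momentum 0.1 running
  statistics, eps 1e-5; statistics are taken over (batch x time) per
  channel, the standard 1-D convention.
* GELU uses the tanh form; ELU uses alpha = 1; softmax subtracts the row
  maximum before exponentiation.
* The MSC kernel ladder 3/5/7 is configurable; the identity path is group 4.
* The stem projection (12 electrodes to 32 channels) is a kernel-1
  convolution — the least-assumption way to enter the stated channel
  width.
* FIT's readout is global average pooling; the baselines use their
  conventional readouts (last step for TCN/LSTM, class token for BERT).
* Ties in `floor`/`ceiling` arithmetic: the learning-rate step happens
  after `floor(epochs/2)` completed epochs; fold boundaries use
  `floor(i * n/k)` cut points so fold sizes differ by at most one frame.
* Weight initialization: Kaiming-normal for convolutions, Glorot-uniform
  for linear maps, uniform `1/sqrt(h)` for the LSTM with a forget-gate
  bias of 1, sd 0.02 for positional/class embeddings.
* `load_ninapro_db2` prefers the refined labels (`restimulus` /
  `rerepetition`) when present — the community standard for DB2 timing —
  and never rescales signal values; the default 10 glove sensors are the
  MCP/PIP flexion channels of a common CyberGlove II layout and are
  configurable, with no claim of matching any particular published subset.

## Known limitations

* The synthetic task is easier than real sEMG regression: the latent space
  is low-dimensional, mixing is linear and stationary, and noise is
  Gaussian. Absolute metric values on synthetic data should not be read as
  predictions of real-data accuracy.
* Training runs on a single CPU core; the implementation is vectorized
  through BLAS but has no GPU path.
* The exact Wilcoxon distribution is enumerated only up to 25 pairs.
* The MAT-file reader covers the numeric-matrix subset of the level-5
  format that Ninapro-style files use (little-endian, real numeric
  classes, optionally zlib-compressed); cells, structs and characters are
  skipped with a warning.
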