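---
title: "Gait identification from inertial sensors: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait identification from inertial sensors: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitid)
```

## The problem

A smartphone in a pocket records tri-axial acceleration while its owner
walks. The pattern of that oscillation — step frequency, the shape of the
heel-strike transient, left/right asymmetries — is distinctive enough to
identify the wearer among a known cohort from about three seconds of
walking. Two obstacles stand between the raw log and a classifier: the
device's orientation on the body is arbitrary and differs between
recordings, and the signal is a long unsegmented stream rather than a set
of labeled examples. `gaitid` addresses both and then fits a recurrent
classifier.

## Orientation-invariant preprocessing

Over any window long enough to span several strides, the oscillatory part
of acceleration averages out while gravity does not. So the per-axis mean
over a centered window of $2m$ samples ($m$ before, $m$ after, window
truncated at the series edges) estimates the gravity direction in the
sensor frame at every instant; dividing by its norm gives the unit vector
$\hat g_i$. Each raw sample is then reduced to its scalar projection

$$\mathrm{acc}_g[i] = \mathbf{acc}[i] \cdot \hat g_i,$$

the vertical acceleration. For a synchronized gyroscope the same
projection, $w_g[i] = \mathbf{w}[i] \cdot \hat g_i$ (using the
accelerometer-derived $\hat g$ — gyroscope means carry no gravity
information), gives the vertical rotation rate. Both are invariant under
any fixed rigid rotation of the device: means rotate covariantly, and dot
products are rotation-invariant. The test suite asserts this to within
$10^{-9}$ over hundreds of random rotations; it is exact up to float
rounding.

Parameters, units, defaults:

* `half_window_m` — gravity half-window, samples. Default 150, i.e.
  $2m = 300$ samples = 6 s at 50 Hz: long enough to average out strides at
  any plausible cadence (1.4–2.6 Hz), short enough to track slow
  orientation drift. The window is implemented as the inclusive centered
  range $[i-m,\, i+m]$ ($2m+1$ points in the interior); shrinking windows
  at the edges keep the output the same length as the input.
* `trim_samples` — samples removed from each end of the projected series.
  Default 150 (3 s at 50 Hz): the start/stop moments of a recording are
  dominated by the subject getting under way and braking, which is noise
  for identification. The amount is a free choice; it is logged with every
  CLI run.
* The projection is kept signed — no absolute value, no filtering, no
  attitude (Kalman/complementary) estimation, no magnetometer. The
  windowed mean is the entire orientation model.

## Windowing and labeling

The scalar series is cut into windows of `window_len` = 150 samples (3 s
at the nominal 50 Hz; 0.02 s/sample) with stride `floor(window_len / 2)` =
75 (half-segment overlap); `stride = window_len` gives disjoint packaging.
Each window carries its subject's 0-based integer label; labels are
one-hot encoded for training. The train/test split draws a uniform random
permutation from a single integer seed and holds out
`round(n * test_fraction)` windows (default 30%).

One caveat is worth stating plainly: with overlapping windows, an
i.i.d. random split lets adjacent (half-shared) windows land on opposite
sides of the partition, so held-out accuracy on a single recording
session overstates what a new session would show. We keep the random
split as the protocol default because it is the field's convention for
this task, and the synthetic checks are unaffected (the subject signal is
stationary by construction); for real deployments a time-blocked split
should be preferred.

Timestamps are treated as metadata after loading: windowing counts
samples, not wall-clock seconds, matching the 150-samples = 3 s
arithmetic at the nominal rate. Foreign sampling rates (e.g. ~200 Hz
exports) are brought to 50 Hz by per-axis linear interpolation — exact for
affine signals, monotone, and free of ringing; fancier kernels would add
assumptions without adding validity.

## The classifier

The network is a stack: LSTM($u_1$) over all $T$ timesteps, emitting its
hidden state at each step; LSTM($u_2$) consuming that sequence and
emitting only its final state; fully connected ReLU layers; a softmax
output with one neuron per subject. Five named presets cover the
benchmarked unit counts (ID1 = LSTM(50, 100) + dense(100, 90) through
ID5 = LSTM(100, 100) + dense(100, 90)). Trainable-parameter counts follow
$4(h(d+h)+h)$ per LSTM layer and $dh + h$ per dense layer — independent of
$T$, since LSTM weights are shared across timesteps; the second LSTM must
emit only its final state for these counts to hold, which pins down the
architecture's read-out. `count_trainable_params()` computes the sum
analytically and the test suite cross-checks it against the weights the
built model actually allocates.

Training is minibatch Adam (step size $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-7}$ — conventional defaults, all
configurable) on categorical cross-entropy, batch 32, with an optional 5%
validation carve-out monitored per epoch. Everything stochastic — weight
initialization, the validation carve-out, shuffling — derives from one
seed, so a fixed seed and fixed data reproduce the training history
bit-for-bit. Gradient correctness is established by a central
finite-difference check in the test suite (worst relative error
$\sim 10^{-6}$), which keeps the hand-written backpropagation honest
independently of any learning outcome.

### Numerical choices that matter

Two backend defaults deserve explanation because the published protocol is
silent on them and the pipeline does not work without them at small
training budgets.

**Constant-offset reparameterization.** The classifier is fed raw
projected values — no per-window normalization — and vertical
acceleration oscillates around $+9.81\ \mathrm{m/s^2}$. That DC component
drives Glorot-initialized LSTM gates deep into saturation (cell states
integrate the constant response, $\tanh'(c) \to 0$, the discriminative
gradient path dies, and no learning occurs within 25 epochs), and even
when training escapes, it couples every input-kernel coordinate to an
effective bias shift of $9.81\,\Delta W$ — a ten-fold amplified, badly
conditioned direction that destabilizes late training. The network
therefore declares the constant component of each input channel
(`input_offset`: 9.81 m/s² for vertical acceleration, 0 for vertical
rotation — a physical constant, not a data statistic) and subtracts it at
its input. Since $W(x - o) + b \equiv Wx + (b - Wo)$, this is exactly a
reparameterization of the first layer's bias, not a data transformation;
the values fed to the model remain the raw projections. Recurrent kernels
are initialized orthogonal per gate and forget-gate biases start at 1,
both standard.

**Gradient clipping.** Backpropagation through 150 timesteps occasionally
produces a gradient spike; beyond the immediate bad step, the spike
poisons Adam's second-moment estimate $v$ (which decays only as
$\beta_2 = 0.999$), collapsing the effective step size and freezing
training at chance for the remaining epochs. Gradients are therefore
rescaled to a global Euclidean norm ceiling (`clip_norm`, default 0.5)
before each update. With clipping, runs that previously collapsed
mid-training converge cleanly.

## The synthetic cohort

The simulator is a signal-level surrogate, not a biomechanical model. A
subject is a profile: a step frequency in 1.4–2.6 Hz, amplitudes and
phases for its first three harmonics (fundamental $O(1.5{-}3)\
\mathrm{m/s^2}$, matching the $\pm 0.3\,g$ excursions typical of pocket
recordings), Gaussian sensor noise, a gyroscope amplitude, and a fixed
random device orientation. The body-frame vertical channel is gravity
plus the harmonic sum plus noise; small out-of-phase horizontal
components and a synchronized gyroscope are built the same way, and the
whole body-frame signal is rotated into the sensor frame. Noise is drawn
in the body frame *before* rotation, so orientation-invariance tests are
exact rather than statistical. In `easy` mode an $n$-user cohort spaces
step frequencies evenly (pairwise gaps $\ge 0.15$ Hz for cohorts of up to
8) with low noise; `hard` mode draws frequencies independently with
higher noise.

The standard study cohort is 8 easy subjects, 120 s each at 50 Hz —
600 windows after preprocessing, sized so the full train/evaluate cycle
runs in about a minute and the whole validation suite in minutes, while
still exercising every pipeline stage; the corpus-geometry checks
separately simulate 15 subjects at 600 s (30,000 samples each) to match a
realistic recording session.

What passing these checks shows: the preprocessing is exactly
orientation-invariant, the bookkeeping (windows, labels, splits,
confusion matrices, parameter counts) is correct, and the classifier can
extract quasi-periodic per-subject structure from raw projected signals
end to end. What it does not show: performance on real gait, where
inter-subject differences are subtler than spaced step frequencies,
within-subject variability (footwear, terrain, fatigue) is real, and
sensors drift. Published accuracies on recorded human corpora cannot be
reproduced from simulation, and this package does not claim them.

## Degenerate inputs and tie-breaks

* A windowed mean with norm $< 10^{-12}$ (stationary, zeroed sensor) is a
  hard error naming the sample index, not a NaN propagated downstream.
* Duplicate timestamps are dropped (first kept, logged); backwards
  timestamps are an error; gaps longer than 3 nominal periods are counted
  in the load report but not repaired — inventing samples would
  manufacture gait where there was none.
* Softmax argmax ties resolve to the lowest class index,
  deterministically.
* `round()`'s round-half-even is used for the test-set size.
* A series shorter than one window yields an empty window set with a
  warning, so a corpus with one short recording degrades instead of
  failing.

## Known limitations

Closed-set identification only — no verification mode, no open-set
rejection, no ROC/EER. The i.i.d. split caveat above. Single fixed device
placement per recording (placement-agnostic, but no cross-placement
transfer model). Training is single-threaded CPU R; at the default
architecture sizes a 25-epoch fit on 600 windows takes on the order of a
minute, which is the intended scale for this package.
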