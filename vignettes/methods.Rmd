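---
title: "Estimating joint angles from vertical ground reaction forces: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating joint angles from vertical ground reaction forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitWNN)
```

## The estimation problem

During walking, the vertical ground reaction force (vGRF) under the foot
and the sagittal rotations of the ankle, knee and hip are two views of the
same underlying motor act. The force is easy to measure unobtrusively
(force plates, instrumented insoles); the angles normally require optical
motion capture or multiple wearable inertial sensors. `gaitWNN` treats
angle acquisition as a regression problem: learn, from paired recordings,
a mapping from salient vGRF samples of one gait cycle to the joint-angle
values at the same instants, then reconstruct the full angle curves.

The central assumptions are (i) that within a homogeneous population
(here: healthy adult gait at self-selected speed) the vGRF waveform and
the angle trajectories co-vary through shared latent gait parameters, so
the mapping is learnable; and (ii) that a gait cycle normalized to 0–100%
of its duration makes those instants comparable across subjects and
trials. Neither assumption holds across very different populations —
pathological gait needs separately trained models.

## Gait-intervals feature selection

A full-length cycle normalized to 100 points is mostly redundant as a
network input. The gait-intervals scheme keeps 22 samples at
biomechanically meaningful instants:

* **Nine primary events** — initial contact (IC), opposite toe off (OTO),
  heel rise (HR), opposite initial contact (OIC), initial toe off (ITO),
  next toe off (NTO), feet adjustment (FA), tibia vertical (TV), next
  initial contact (NIC). IC, ITO, NTO and NIC come from measured event
  timings; OTO, HR, OIC, FA and TV default to normative phase indexes
  (10, 30, 50, 73, 87% — configurable) snapped to the grid inside a ±1%
  buffer.
* **Thirteen intermediate events** subdividing the seven sub-phases
  (loading response; mid and terminal stance; pre-, initial, mid- and
  terminal swing with 1, 2, 2, 1, 2, 3, 2 events respectively). A
  sub-phase from $t_{start}$ to $t_{end}$ with $n$ intermediate events
  uses the step $b = (t_{end} - t_{start})/(n+1)$; the $k$-th event sits
  at the grid point nearest $t_{start} + kb$, within the same ±1% buffer.

In a stance-first cycle the stance-to-swing transition is one physical
instant carrying two event labels (ITO and NTO); it is split into
adjacent indexes $t-1$ and $t+1$. After assembly, any duplicate index is
shifted +1% until unique, scanning in feature order; the schedule must
remain strictly increasing or the cycle is rejected. Swing-phase features
(numbers 12–22) are read from the *opposite* leg's vGRF — the swing foot
carries no load — and negated so their numeric range cannot collide with
stance features. Each cycle thus yields a 22-vector of inputs and a
66-vector of targets (ankle, knee, hip at all 22 events).

Numerical choices worth stating: grid resolution is fixed at 1% (101
points, indexes 0–100); snapping uses round-half-up, since the interval
rule frequently produces exact .5 positions and a deterministic tie-break
keeps schedules reproducible; the dedup scan moves the later-numbered
feature, leaving primary events in place where possible.

## The wavelet network

The estimator is a two-layer network whose hidden nodes ("wavelons") are
products of translated, dilated Mexican-hat wavelets
$\psi(z) = (1-z^2)e^{-z^2/2}$, plus a direct linear input–output path and
output biases:

$$\hat y_j = \sum_{i=1}^{N^h} \psi_i(\mathbf{x})\,\omega_{ij}
           + \sum_{k=1}^{N^l} x_k\,\omega_{kj} + b_j,\qquad
  \psi_i(\mathbf{x}) = \prod_{k=1}^{N^l}
      \psi\!\left(\frac{x_k - \omega_{(\xi)ki}}{\omega_{(\varsigma)ki}}\right).$$

The Mexican hat is even, has unit value at 0, zeros at ±1 and zero mean;
its localized support is what gives wavelons their compression advantage
over sigmoids, and also what makes initialization critical: a wavelon
whose active region misses the data contributes nothing and receives no
gradient.

**Initialization.** Translations are set to the midpoint of each input's
training range and the output biases to the target means. For the
dilations we depart from a literal reading of the published heuristic,
which scales the (negative) range by 100 under a cap of 1: at
body-weight-scaled inputs that yields dilations of order $10^{-3}$,
i.e. $|z| \sim 10^2$ — every wavelon numerically dead and the model
silently reduced to its linear path. We set the dilation to *half the
input range* (capped at 1, floored at $10^{-3}$ for constant inputs, the
scale configurable via `dilation_scale`), which places each input's
observed range inside the wavelet's active $[-2, 2]$ core — the stated
intent of the heuristic. Note the first feature (vGRF at IC) is
identically zero by construction, so its dilation is floored and a
warning is raised; this is expected.

**Training.** The cost is the per-sample sum of squared output errors
averaged over samples, minimized by full-batch gradient descent with
momentum ($v \leftarrow \mu v - \eta \nabla L$, parameters += $v$).
Gradients are analytic throughout, including through the wavelon product
(using $\psi'(z) = z(z^2-3)e^{-z^2/2}$ and leave-one-out products
computed by prefix/suffix cumulative products, which stay exact when a
factor crosses zero). Defaults: learning rate 0.01, momentum 0.9, at
most 50 epochs, stop early if the cost reaches $10^{-5}$. These two
optimizer constants are not dictated by the method and live in
`training_config()`. The hidden-layer size is chosen by minimum
prediction risk — the same cost functional on a held-out 30% — over a
candidate set, ties toward the smaller network; five nodes is the
default. The sigmoid MLP baseline (`mlp_baseline()`) shares the cost,
optimizer, budget and bias initialization, differing only in its
hidden-layer activation and the absence of the direct linear path.

## Evaluation protocol

Samples are shuffled into three independent 70/30 train/test sequences
(`make_splits()`, `round(0.7 n)` training samples). For each sequence the
network is trained and all samples are predicted; per sample and joint
the 22 predicted angles are expanded to a 101-point profile by a cubic
spline through the (event index, angle) knots and compared with the
measured profile via RMSE (degrees), NRMSE and Pearson $\rho$. Scores are
computed per profile and then averaged (mean ± SD) over all samples and
separately over in-sample and out-of-sample subsets; the sequence with
the least mean RMSE is reported.

Two conventions here were genuinely open. The NRMSE normalizer is the
ground-truth profile's range (max − min), not its mean — sagittal angle
means sit near zero, which would make a mean-normalized error explode.
The spline uses Forsythe–Malcolm–Moler end conditions (`stats::spline`,
`method = "fmm"`), which fit exact cubics through the boundary knots:
unlike natural end conditions (second derivative forced to zero) this
reproduces polynomial trends at the cycle boundaries exactly, and in
particular recovers any cubic target identically — the property the test
suite checks. Scoring on reconstructed 101-point profiles (rather than on
the 22 samples) matches how the estimates would be used downstream.

## The synthetic cohort

The original motion-capture cohort (300 samples: 30 adults × 10 trials)
is not publicly deposited, so the package generates surrogate data with
the statistical structure the estimator assumes; all distributed
fixtures are produced by code.

* **vGRF**: the classic double-bump stance curve — Gaussian loading and
  push-off peaks (defaults 1.10 and 1.15 body weight at 13% and 48% of
  the cycle) over a 0.75 BW mid-stance plateau, tapered smoothly to zero
  at contact and toe-off (~60%), exactly zero through swing. The
  contralateral signal is the same waveform offset by half a cycle.
  Forces are in body-weight units, so no anthropometrics are needed.
* **Angles**: order-4 Fourier templates fitted to normative sagittal
  curves, scaled per subject about their mean value. Template excursions
  stay inside the published normative 95% envelopes (ankle
  [−24.8, 16.1]°, knee [−4.9, 72.4]°, hip [−24.1, 33.2]°) with margin
  for subject scaling and noise.
* **Variability and coupling**: each subject draws a cadence scale, a
  latent force amplitude, angle scales *coupled to that amplitude*, and
  timing offsets (|shift| ≤ 3% of the cycle); trials add timing jitter
  (SD 0.5% by default) and measurement noise (vGRF SD 0.02 BW on stance
  samples only; angle SD ten times that in degrees). The shared latent
  parameters are what make the vGRF→angle mapping identifiable; in real
  recordings the analogue of this coupling is simply that both signals
  come from the same legs.

What the generator does **not** emulate: ground-truth event-detection
error, inter-leg asymmetry, soft-tissue and marker artefacts, fatigue or
speed drift across trials, and any pathological pattern. Passing tests
on this cohort therefore validate the pipeline's mechanics and the
estimator's statistical behaviour under its own assumptions — not
clinical accuracy on real gait, whose headline errors cannot be
reproduced without the original recordings.

## Preprocessing

Raw channels are filtered with a first-order Butterworth low-pass applied
forward and backward, so event timings are not phase-shifted. The design
cutoff is pre-compensated in the warped frequency domain so that the
*dual-pass* response is −3 dB at the nominal cutoff, and the signal is
reflectively padded so the filter enters the data in steady state. The
per-channel cutoff is estimated as the lowest frequency whose cumulative
FFT power reaches 99% of the total; because a first-order roll-off is
shallow, the pipeline clamps estimated cutoffs to 10–20 Hz — below that
the 3rd–4th gait harmonics (3–5 Hz at typical cadence) lose several
percent of amplitude and angle waveforms visibly distort (a first-order
filter at 15 Hz still alters a noiseless synthetic cycle by up to
~0.4° at the knee; the test suite bounds this). Samples where the
measured force is exactly zero are kept at zero after filtering: the
foot-off-ground constraint is physical, not spectral. Cycles are then
sliced between measured boundary events (IC→NIC by default) and linearly
resampled to the 101-point grid, with boundary events mapping exactly to
0 and 100%.

Degenerate inputs are rejected rather than repaired: non-monotone time
vectors, boundary events closer than 10 samples, schedules whose dedup
pass breaks ordering, constant ground-truth profiles (NRMSE undefined).

## Problem sizes and determinism

All shipped analyses are desk-scale: the default experiment (300
samples, three sequences, WNN + MLP at 5 nodes / 50 epochs) runs in a
few seconds; the teacher-student recovery study uses a
3-input/3-wavelon/2-output teacher with 200 training and 200 test
samples, 2000 epochs, noise SD 0.2 (observed held-out risk ≈ 0.09
against a noise floor of 2σ² = 0.08). Every stochastic step takes an
explicit seed; `derive_seed()` fans a single master seed out to the
generator, initialization and split stages, and fixed seeds reproduce
cohorts, fits and reports bit-identically.

## Known limitations

Healthy adult sagittal gait only; one network per population is the
intended usage pattern. The ITO→NTO cycle convention is supported for
partitioning/normalization, but event schedules are defined on IC-origin
cycles (a swing-first cycle must be rotated first). The pre-defined
primary-event indexes are normative stand-ins, not subject-specific.
First-order filtering trades waveform fidelity for simplicity; users
with noisier hardware should pass an explicit cutoff. The momentum
optimizer is full-batch by design — inputs are 22-dimensional — and no
minibatch or second-order paths are provided.
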