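---
title: "Methods: two-stage Edi peak detection and neural-breathing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage Edi peak detection and neural-breathing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edipeaks)
```

## The signal and its units

The electrical activity of the diaphragm (Edi) is a rectified, processed EMG
envelope streamed by the ventilator at 100 Hz in microvolts. Every neural
inspiration raises the envelope from a tonic floor (≈1 µV in preterm
infants) to a peak (commonly 5–20 µV) and decays back during neural
expiration. All internal time bookkeeping uses the integer sample index;
every user-facing duration (Ω, δ, t, epoch lengths) is specified in
milliseconds or seconds and converted through the sampling rate. At 100 Hz
the matching tolerance δ = 140 ms is exactly 14 samples.

## Stage one: candidate over-detection

A sample is a candidate peak when it attains the maximum of the centered
window of length `omega_lm_ms` (default 270 ms, half-width
`w = round(Ω/2 · fs)` samples). The window must fit inside the recording, so
the first and last `w` samples yield no candidates. Two numerical choices
matter:

* **Plateau tie-break.** With a non-strict maximum every sample of a flat
  stretch qualifies; only the leftmost sample of each equal-valued run is
  emitted. Exact ties essentially never occur in real envelopes but are
  routine in synthetic or clipped data.
* **Nesting.** For tie-free signals the candidate set of a larger window is
  a subset of that of a smaller window; the package's property tests assert
  this on continuous-valued random signals. Exact plateaus can break the
  inclusion at window borders, which is one more reason the tie-break is
  pinned down explicitly.

The window length trades recall against classifier load: 270 ms is short
relative to the neonatal breath (≈1.2 s at 50 breaths/min) so true peaks are
essentially never missed, while artifact maxima pass through freely — by
design, since the second stage exists to remove them.

## Stage two: the classifier

Each candidate becomes a fixed-length window (`window_len` = 256 samples =
2.56 s) centered on the candidate, zero-padded at recording edges and
z-normalized per window (an all-constant window becomes all zeros).
Fixed-length windows rather than variable-length breath segments keep
batching trivial; the global-average-pooling head would accept any length,
and 2.56 s covers one neonatal respiration with context on both sides.

The network is a 1D grouped-convolution residual network in the ResNeXt1D
family: a stem convolution, `n_block` pre-activation residual blocks (batch
norm → ReLU → grouped conv, twice), parameter-free shortcuts (max-pool at
downsampling blocks, zero channel padding at widening blocks), then batch
norm, ReLU, global average pooling and a dense layer to two logits. The full
configuration — kernel 16, stride 2, 48 blocks, downsampling every 6 blocks,
channel doubling every 12 from 352 base filters, input dimension 1, output
dimension 2 — is the published one for this backbone family.

**Cardinality.** The number of convolution groups is not part of the printed
configuration, but the model's documented size (≈248 million trainable
parameters) pins it down. With two grouped 16-tap convolutions per block the
count is ≈496 M at 8 groups, ≈248 M at 16 and ≈124 M at 32; a 1-16-1
bottleneck block with 32 groups lands near 316 M. Only the two-convolution
block with **cardinality 16** reproduces the printed size (the package
builds it at 247.95 M), so that is the default; both the block style and the
group count are ordinary config fields should a different variant be wanted.

**Training schedule.** Adam (β₁ = 0.9, β₂ = 0.999) with minibatch 32,
initial learning rate 10⁻³ and L2 weight decay 10⁻³ folded into the
gradient; a seeded random 80/20 train/validation split; learning rate ×0.1
after 5 epochs without validation-loss improvement; stop after 7 such
epochs or at `max_epochs`; the weights of the best validation epoch are
restored. The schedule logic lives in a small pure state machine
(`plateau_init`/`plateau_step`) so its contract is directly testable.
Class weighting for the over-detection imbalance is available
(`class_weights = "balanced"`) but off by default.

**Implementation.** The forward/backward passes are written in the package
itself: grouped convolutions run through compiled im2col + GEMM kernels
(RcppArmadillo), with a pure-R reference implementation retained and the two
asserted equal in the unit tests; batch norm, pooling and the optimizer are
plain R. Analytic gradients are checked against central differences in the
test suite. Training is deterministic given the seed and BLAS backend.

The `tiny` preset (6 blocks, 16 base filters, 4 groups, downsample every 2,
widen every 4; ≈24 k parameters) is the workhorse for testing and the
synthetic benchmark; the full 248 M-parameter model is instantiated for the
size measurement but never trained in the suite.

## Breath segmentation and asynchrony

Between adjacent peaks the boundary rule looks for the first sample that is
the minimum of its centered `omega_re_ms` window (150 ms) *and* lies below
`sigma` (0.5) times the smaller flanking peak amplitude; scanning backward
from the later peak yields the inspiration onset, forward from the earlier
peak the expiration end. The window must lie inside the open inter-peak
interval. If no sample qualifies (e.g. elevated tonic activity), the gap's
global minimum is used and the breath is flagged rather than dropped, so
respiratory-rate counts stay usable. Breaths are assembled only for peaks
with both boundaries available, so the first and last peak of a recording do
not form complete breaths.

Inflations are detected from the pressure channel as maximal runs above
`baseline + 0.5·(peak − baseline)`, with baseline/peak taken as the 10th/95th
percentiles (PEEP plateau and near-PIP); runs closer than 100 ms are merged,
runs shorter than 100 ms dropped. These thresholds are package choices (the
clinical provenance of "a positive-pressure ventilation" from raw channels
is not standardized) and are config-exposed.

Double triggering: ≥ 2 inflation *starts* within one breath's
onset–offset interval; the episode is the breath interval. Autotriggering: a
gap from expiration end to the next inspiration onset longer than `t` = 5 s
containing inflation starts; each such inflation is one event (a long apnea
with k inflations is k events, reported per hour).

## Evaluation protocol

δ-tolerance one-to-one peak matching defines TP/FP/FN; precision, recall and
F1 use the usual count formulas with 0/0 → 0. The matching is greedy by
increasing distance with a leftmost tie-break; its maximality is verified
against an order-preserving dynamic-programming maximum matching (exact for
points on a line) and the DP assignment substitutes in the rare adversarial
configurations where greedy drops a pair, so the TP count is always maximal.
R² uses the mean-square form `1 − SSE/SST` on epoch-wise respiratory rates
(epoch default 60 s — rate is conventionally per minute; the synthetic
benchmark uses 30 s epochs so that 180-s recordings contribute several
epochs per patient). Per-patient metrics are aggregated as mean and
population standard deviation; R² is averaged per patient rather than pooled
across epochs, matching the mean-(SD) reporting convention. Event lists are
matched one-to-one by largest interval overlap. Interpatient folds shuffle
patients by seed and deal round-robin, so fold sizes differ by at most one
and `k = n` reproduces leave-one-out.

## The synthetic generator

The generator emulates what the detectors must survive, not lung mechanics:

* **Breath train.** Intervals are Gaussian around 60/`rr_mean` s
  (`rr_mean` 50/min, CV 0.08), truncated at the 150 ms minimum spacing.
  Peak amplitudes are Gaussian (mean 12 µV, CV 0.2) with a floor at half the
  mean. Each pulse rises as a raised cosine over 35 % × 95 % of its
  preceding inter-peak gap and decays as a truncated exponential
  (τ = decay/4) over 65 % × 95 % of its following gap, so every neural
  silence is 5 % of its own gap regardless of interval jitter. The
  exponential expiratory limb matters twice: it gives the apex a sharp,
  noise-robust location (a raised-cosine decay left the apex flat over more
  than δ, making the "true" peak position ill-defined), and its long flat
  tail hosts abundant false local maxima, reproducing the candidate stage's
  characteristic ~0.6 precision / ~1.0 recall signature on noisy neonatal
  data.
* **Noise.** White noise (SD 0.3 µV), periodic cardiac spikes (0.8 µV at
  150/min), sinusoidal baseline wander (0.5 µV, 20 s), Poisson peristalsis
  bursts (2/min, ≈4 µV, ≈2 s — wide, slow bumps that create plausible false
  peaks), and Poisson electrode-motion transients (10/min, ≈3 µV, 0.25 s —
  sharp spikes, the main false-candidate source). These defaults are the
  package's "moderate noise" condition; zero everything for the clean limit.
* **Ventilator channel.** PEEP 5 / PIP 15 cmH₂O; one inflation per breath
  triggered 120 ms after the neural onset (a representative
  neural-to-pneumatic latency; an implausibly fast trigger makes
  onset-boundary jitter reclassify the breath's own inflation) and cycled
  off just past the Edi peak. Injected double-trigger events add a second
  inflation at 20 % of the expiratory decay (an immediate re-trigger);
  injected apneas (> t) host autotrigger inflations.
* **Determinism.** All randomness flows from one seed; benchmark patients
  get independent streams via a stable string hash of the patient id, so a
  patient's data do not depend on how many patients are generated.

What passing tests on this generator shows: the detectors and metrics behave
correctly on signals with the stated morphology and artifact classes. What
it does not show: performance on real neonatal recordings, whose artifacts
are not stationary Poisson processes, whose breath shapes vary more richly,
and whose annotation is itself uncertain.

## Problem sizes

The end-to-end checks use a 10-patient benchmark of 180-s recordings at
moderate noise with a single interpatient hold-out split (7 train / 3 test)
for the tiny classifier, 30-s rate epochs, and 600-s recordings (5 apneas,
2 double-triggers/min) for event recovery; oracle suites run on dozens of
seeded random signals. These sizes give stable statistics (≈1 500 labeled
candidates, ≈20–40 injected events per kind per noise level) while a full
run of suite plus acceptance script stays within a coffee break on one CPU.

## Known limitations

* The classifier cannot recover peaks the candidate stage missed; recall is
  bounded by stage one.
* Boundary localization inherits the window-minimum rule's blur on flat
  valleys (≈ half a window); onsets are accurate to ≈100 ms only when
  expiration decays close to the next inspiration.
* Only double triggering and autotriggering are modeled; other asynchrony
  types (ineffective efforts, premature cycling) are out of scope, as is any
  real-time / streaming use.
* The full-size model is built and counted but not trained here; training
  it requires GPU-scale resources.
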