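---
title: "Detecting slow eye movements from bimodal EOG/EEG: models and methods"
author: "semscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting slow eye movements from bimodal EOG/EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semscan)
```

## The problem

Slow eye movements (SEM) are slow, rolling, sinusoidal, conjugate
horizontal eye movements that mark the sleep onset period. On two
electrooculogram electrodes placed at the outer canthi (`Hl`, `Hr`) a
conjugate horizontal movement appears with *opposite phase*, while
brain-electrical activity appears as a *common mode*. Two derived channels
therefore separate the sources:

* `HEOG = Hl - Hr` doubles the eye movement and cancels the EEG;
* `HSUM = Hl + Hr` cancels the eye movement and doubles the EEG-like
  common mode, behaving as a surrogate for an occipital electrode (`O2`)
  in the alpha band.

`semscan` turns SEM detection into a binary classification of 3-s window
samples from the bimodal pair (`HEOG`, `HSUM`) or (`HEOG`, `O2`), using a
parallel two-branch CNN-Transformer. Everything runs end to end on
simulated recordings, so each stage is testable without any recorded data.

## The synthetic generator

`simConfig()` / `simulateRecording()` compose, at 500 Hz:

* **SEM events**: Tukey-tapered (10% taper) sinusoids, frequency 0.2-0.6 Hz,
  peak amplitude 30-150 uV, duration 3-7 s, inter-channel onset difference
  0-150 ms; added with opposite signs to `Hl`/`Hr`. Events are placed
  uniformly at random without overlap, with 1-s guard gaps (rejection
  sampling, 1000 attempts). The taper keeps event onsets well defined
  without step artifacts above 1 Hz.
* **Saccades** during alert periods: opposite-phase linear-rise steps
  (20 ms rise, 0.5 s plateau, mirrored return), 50-200 uV.
* **Common-mode EEG**: pink (1/f) background band-limited to 0.1-30 Hz
  (SD 5 uV) plus alpha bursts - a sinusoidal carrier at 8-13 Hz,
  amplitude-modulated by a smooth random envelope with ~1 s bursts
  (0.8 Hz envelope bandwidth), peak amplitude 35 uV. Inside SEM intervals
  the alpha amplitude is multiplied by 0.3, mirroring the attenuation of
  alpha as sleep onset approaches.
* **O2**: shares the alpha burst waveform of the common mode but has its
  own independent pink background and sensor noise, which reproduces a
  high but imperfect alpha-band correspondence between `O2` and `HSUM`.
* **Drift and noise**: a shared 0.05 Hz baseline drift (15 uV) and
  independent white sensor noise (SD 3 uV) per channel.

The alpha amplitude (35 uV, i.e. 70 uV peak-to-peak) and the ~1 s burst
timescale were calibrated once so that the generator meets its own design
contract - a median per-sample alpha-energy correlation between `O2` and
`HSUM` above 0.7 under the default configuration - while staying within
the physiological range of prominent eyes-closed occipital alpha. Smaller
amplitudes or slower envelopes leave too little *within-window* shared
envelope variation and the correlation collapses, which is not what real
eyes-closed recordings show.

**What the simulator does not emulate**: blinks and vertical EOG, head
and electrode-motion artifacts, non-stationary alpha frequency, ambiguous
or borderline SEM morphology, inter-subject variability. Its two classes
are cleanly separated by construction; consequences for what tests can
show are discussed under *Limitations*.

## Preprocessing

* `medianSmooth()` - sliding median, window 10 samples (even window:
  mean of the two central order statistics), reflect padding; applied to
  `HEOG`.
* `removeBaselineDWT()` - Daubechies-2 discrete wavelet transform,
  symmetric signal extension, decomposition depth 10; the reconstructed
  level-10 approximation (roughly 0-0.24 Hz at 500 Hz) is subtracted from
  the signal. Applied to `O2` or `HSUM`. The filter bank is implemented in
  the package (verified for perfect reconstruction and against reference
  db2 coefficients); no additional digital band-pass is applied because
  acquisition-stage band-limiting is emulated inside the simulator.
* Preprocessing runs on the continuous recording *before* windowing to
  avoid per-window edge artifacts; windows (3 s at 500 Hz = 1500 samples)
  are then decimated by 3 to 500 samples. The signals are band-limited to
  30 Hz, so decimation to a 83 Hz Nyquist needs no anti-alias filter.

## The labeling criteria as an executable validator

`checkSemCriteria()` renders the visual marking rules executable. Measured
on 0.2-s moving-average smoothed, linearly detrended channels (the criteria
describe the slow excursion, not the superimposed EEG):

| verdict | measure | rule |
|---|---|---|
| phase_opposition | Pearson r(Hl, Hr) | <= -0.8 |
| frequency_band | periodogram peak of HEOG; edge rate | 0.2-0.6 Hz (7% edge tolerance); max slope / peak <= 12 /s |
| duration | epoch length | > 2 s |
| amplitude | max abs(HEOG) / 2 | 20-200 uV |
| onset_difference | cross-correlation lag of Hl vs -Hr | <= 300 ms |
| artifact_free | max abs raw sample | <= 500 uV |

Three measures deserve comment. (1) The dominant frequency of a finite,
tapered, noisy epoch is biased by up to a few percent near the band edges,
so the frequency verdict carries a small relative tolerance; without it,
legitimate events at exactly 0.6 Hz fail. (2) A mean-removed saccadic
plateau has its periodogram peak *inside* the SEM band (around 0.5 Hz for
a 1 s plateau in a 3 s epoch), so a bare periodogram rule cannot reject
saccades; the edge-rate guard (max slope of the lightly smoothed difference
trace divided by its peak, <= 12 /s) separates them cleanly - sinusoids at
0.6 Hz stay below ~8 /s, saccadic steps exceed 20 /s. This implements the
requirement that SEM be *slow*, clearly different from the saccade.
(3) Per-channel 25%-threshold onset detection is corrupted by common-mode
EEG background once each channel is detrended separately; the
cross-correlation lag between `Hl` and `-Hr` measures the same quantity
robustly and exactly on clean events.

Windows fully contained in one labeled epoch inherit its label; windows
straddling an epoch boundary are discarded. The chronological split
reserves the last 30% of windows for testing; the five cross-validation
folds are contiguous time blocks, because neighbouring windows overlap by
97% and shuffled folds would leak.

## The classifier

Each branch of the parallel bimodal network processes one 500-sample
modality vector:

conv(k, 64 filters) -> BN -> ReLU -> conv(k, 64) -> BN -> ReLU ->
max-pool(4) -> + sinusoidal positional encoding -> 2 Transformer encoder
layers (2 heads, post-norm, FFN width 128) -> global average pooling.

The two 64-dimensional branch outputs are concatenated (128) and pass
through FC(64)-ReLU-dropout(0.5)-FC(2)-softmax. Kernel sizes come from the
grid {50, 150, 250} (the demo and acceptance runs use 50 throughout, the
cheapest grid point). Baselines substitute the Transformer with nothing
(CNN), an LSTM (CNN-LSTM; units from {50, 100, 150}, sequence output then
GAP), or an LSTM with additive attention pooling. Ablations remove the
Transformer, the convolution module (replaced by a per-timestep linear
embedding so the encoder still receives 64 features; max-pooling is kept so
the attention cost stays bounded), residual connections, or the FFN
sub-layers.

Choices the source architecture leaves open, fixed here: filter count =
`d_model` = 64 so convolution output feeds the encoder without projection;
`d_ff` = 128 (2 x d); pool size 4 (encoder length 125); sinusoidal (not
learned) positional encoding; post-norm Add&Norm as written; layer-norm
epsilon 1e-5; classifier FC1 width 64; additive (Bahdanau-style) attention
for the LSTM-attention baseline. All are config-exposed.

### Training

Weighted cross-entropy `L = -sum_i w_i y_i log(p_i)` with inverse-frequency
class weights `w_i = N / (c N_i)` computed on the training split (their
frequency-weighted mean is exactly 1); Adam (beta1 0.9, beta2 0.999),
initial learning rate 5e-4 reduced by 0.2 after 3 stagnant validation-loss
epochs (floor 1e-6), minibatch 128, early stopping after 10 stagnant
validation-accuracy epochs with best-weights restoration. The validation
set is the chronological tail 10% of the training portion. A fixed seed
reproduces initialization, batch order and dropout exactly.

All layers and their gradients are implemented in the package (R matrix
algebra with compiled kernels for convolution, pooling and attention;
float32 convolution arithmetic, the customary deep-learning precision).
Every gradient is verified in the test suite against double-precision
references and central finite differences.

One training-dynamics choice differs from common framework defaults:
batch-norm inference moments are tracked as a *cumulative average of batch
statistics, restarted each epoch*, not a momentum-0.99 exponential moving
average. With the short schedules used here (~16 minibatches per epoch) a
0.99 EMA is nowhere near converged, which makes inference-mode validation
- and therefore early stopping - meaningless. The cumulative average is
exact after any number of batches and converges to the same limit for long
runs.

## Evaluation and analysis

`confusionMetrics()` reports TP/TN/FP/FN with precision, recall, accuracy
and F1 as percentages (SEM positive, argmax threshold). `prCurve()` sweeps
all score thresholds and integrates by the average-precision step rule.
`aggregateReports()` averages metrics over subjects; the printed +/- spread
uses the population SD (n denominator), which is the convention the
published per-subject tables follow (a sample SD is available via flag).

`cwtAlphaEnergy()` computes a complex-Morlet continuous wavelet transform
(centre frequency 1.0, bandwidth 1.5, L1-normalized kernels) over 6-14 Hz
in 0.25 Hz steps and averages coefficient magnitudes across frequency into
a time-varying energy curve. `energyCorrelation()` correlates the `O2` and
`HSUM` curves over non-overlapping 3-s samples, removes samples whose
correlation deviates from the mean by more than twice the SD (single
pass), and summarizes by the median. `extractAttention()` and
`classAverageAttention()` capture the row-stochastic encoder attention
maps during an instrumented forward pass (which provably does not change
the outputs) and average them per true class.

## Problem sizes

The packaged study simulates one 400-s recording with 14 SEM episodes,
yielding ~3,200 windows at ~10% SEM prevalence; training uses one epoch of
the Adam schedule (the task saturates within the first epoch; see below).
The acceptance suite additionally validates the labeling criteria on 200
generated events and 200 control epochs, and the layer primitives against
brute-force oracles on 110 random instances each.

## Limitations, and what passing tests do not show

* The synthetic task is *easy by construction*: SEM events are 30-150 uV
  band-limited oscillations on an ~8 uV background. The full
  CNN-Transformer reaches a perfect test F1 within one epoch - but so does
  the CNN-only ablation. The package's own acceptance experiment therefore
  shows a clear margin over the Transformer-only ablation, while the
  CNN-only comparison saturates at a tie; the advantage of global temporal
  modeling that the architecture was designed for manifests on ambiguous
  real recordings, not on this simulator. Passing the synthetic study
  validates the implementation (pipeline, gradients, training dynamics),
  not the architectural superiority claim.
* The criteria validator assists but does not replace expert marking; its
  thresholds (phase -0.8, artifact 500 uV, edge rate 12 /s) were chosen to
  separate the simulator's classes cleanly and are config-exposed.
* Models are subject-specific by design; cross-subject transfer is out of
  scope.
* EDF support covers the subset of the format the package writes
  (16-bit, 1-s records, uV); the window container is Parquet.
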