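# semscan — slow eye movement detection from bimodal EOG/EEG signals

Slow eye movements (SEM) are the slow (0.2–0.6 Hz), rolling, sinusoidal,
conjugate horizontal eye movements that mark the transition from
wakefulness to sleep — a physiological warning sign of driver sleepiness.
On two EOG electrodes at the outer canthi (`Hl`, `Hr`), a conjugate eye
movement is opposite-phase while EEG activity is common-mode, so two
derived channels separate the sources:

    HEOG = Hl − Hr   (isolates eye movement)
    HSUM = Hl + Hr   (cancels eye movement, keeps EEG-like activity)

`semscan` detects SEM by classifying 3-s bimodal window samples
(`HEOG` + `HSUM`, or `HEOG` + occipital `O2`) with a **parallel bimodal
CNN-Transformer**: per modality, two 1-D convolution layers (batch norm,
ReLU), max-pooling, sinusoidal positional encoding, two post-norm
Transformer encoder layers

    H_i = Softmax(Q_i K_i' / sqrt(d_k)) V_i,    i = 1..h
    Z~  = Concat(H_1..H_h) W_O
    O   = LN(Z_mid + FFN(Z_mid)),  Z_mid = LN(Z + Z~),  FFN(x) = max(0, xW_1+b_1)W_2 + b_2

and global average pooling; the two 64-dimensional branch features are
concatenated and classified by two fully connected layers with softmax.
Training minimizes the weighted cross-entropy
`L = −Σ_i w_i y_i log(p_i)` with inverse-frequency class weights
`w_i = N / (c·N_i)`, Adam (lr 5e-4, adaptive decay), minibatch 128 and
accuracy-monitored early stopping. CNN, CNN-LSTM and CNN-LSTM-attention
baselines and component ablations share the same contract.

The package is self-contained: a seeded synthetic generator produces
recordings with ground-truth SEM intervals (opposite-phase tapered
sinusoids, saccadic steps, alpha bursts that attenuate during SEM, drift,
noise); the visual SEM labeling criteria are implemented as an executable
validator; every network layer and its gradient is implemented and
verified in-package (compiled kernels for convolution/pooling/attention).
Supporting tools: median smoothing and Daubechies-2 wavelet baseline
removal, CSV/EDF/Parquet I/O, precision–recall evaluation, alpha-band
complex-Morlet energy-correlation analysis, and encoder attention-map
extraction.

## Worked example

```r
library(semscan)

rec   <- simulateRecording(simConfig(duration_s = 120, n_sem_events = 5,
                                     n_saccades = 10, seed = 1))
prep  <- preprocessRecording(rec, "HSUM")     # median-smooth + DWT baseline
ws    <- extractWindows(prep)                 # 3-s windows, 0.1-s step
split <- chronologicalSplit(ws)               # first 70% train, last 30% test
model <- fitModel(ws, split$train, modelConfig(),
                  trainConfig(max_epochs = 2, seed = 1))
ev    <- evaluateModel(model, ws, split$test)
ev$report
#> EvalReport: 9 pos / 256 neg, FP=0 FN=0
#>   precision 100.00%  recall 100.00%  accuracy 100.00%  F1 100.00%
```

The held-out report counts true/false positives and negatives over the
chronological test windows; on this short, cleanly simulated recording the
classifier separates the classes perfectly (see the methods vignette for
why that is expected and what it does and does not demonstrate). The
alpha-band analysis supports `HSUM` as a two-electrode surrogate for
occipital EEG:

```r
ec <- energyCorrelation(rec)
round(ec$median_r, 2)
#> [1] 0.86
```

A command-line front end (`exec/semscan`) exposes the same stages as
subcommands (`simulate`, `preprocess`, `label`, `windows`, `train`,
`evaluate`, `cwtcorr`, `attention`, `demo`).

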