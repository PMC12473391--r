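Package: semscan
Title: Slow Eye Movement Detection from Bimodal EOG/EEG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of slow eye movements (SEM), the slow rolling
    conjugate horizontal eye movements that mark the sleep onset period,
    from bimodal electrooculogram/electroencephalogram recordings. Provides
    a seeded synthetic signal generator with ground-truth SEM intervals, the
    HEOG/HSUM channel derivation and cleaning chain (median smoothing,
    Daubechies-2 wavelet baseline removal), an executable implementation of
    the visual SEM labeling criteria, sliding-window dataset construction
    with chronological splits, a parallel bimodal CNN-Transformer classifier
    with weighted cross-entropy training (plus CNN, CNN-LSTM and
    CNN-LSTM-attention baselines and ablation variants), confusion-matrix
    and precision-recall evaluation, alpha-band Morlet wavelet energy
    correlation analysis, and self-attention map extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    arrow,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
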