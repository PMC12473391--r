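# small shared fixtures, generated in code

smallSimConfig <- function(seed = 1, ...) {
  simConfig(duration_s = 60, n_sem_events = 3, n_saccades = 4,
            seed = seed, ...)
}

# tiny window set with a learnable class structure: class 1 windows carry a
# slow high-amplitude sinusoid on modality 1
toyWindowSet <- function(n = 60, len = 40, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  t <- seq_len(len) / len
  x1 <- sapply(y, function(lab)
    if (lab == 1) 3 * sin(2 * pi * t) + rnorm(len, 0, .3)
    else rnorm(len, 0, .3))
  x2 <- sapply(y, function(lab)
    if (lab == 1) rnorm(len, 0, .3) else 1.5 * cos(2 * pi * t) + rnorm(len, 0, .3))
  semscan:::newSemWindowSet(x1, x2, y, seq_len(n) * 0.1,
                            meta = list(fs = 500, win_s = 3))
}

tinyModelConfig <- function(variant = "cnn_transformer", ...) {
  modelConfig(variant, kernels = c(5, 3, 5, 3), d_model = 8, heads = 2,
              n_layers = 1, d_ff = 16, pool = 2, lstm_units = 6,
              dropout = 0, fc1 = 8, ...)
}
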