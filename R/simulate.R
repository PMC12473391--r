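#' Simulation configuration
#'
#' Parameters of the synthetic bimodal EOG/EEG generator. Defaults describe a
#' mildly sleep-deprived subject drifting in and out of the sleep onset
#' period: occasional slow-eye-movement (SEM) episodes on a background of
#' alert activity with saccades, occipital-style alpha bursts that attenuate
#' during SEM, slow electrode drift, and broadband noise.
#'
#' SEM events are opposite-phase slow sinusoidal excursions on the two
#' horizontal EOG channels, constrained to the visual labeling criteria:
#' frequency 0.2-0.6 Hz, amplitude 20-200 uV, duration > 2 s, inter-channel
#' onset difference <= 300 ms.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param n_sem_events number of SEM episodes to place.
#' @param sem_freq_range SEM sinusoid frequency range (Hz), inside [0.2, 0.6].
#' @param sem_amp_range SEM peak amplitude range (uV), inside [20, 200].
#' @param sem_duration_range SEM duration range (s), lower bound > 2.
#' @param onset_diff_max_ms maximum inter-channel onset difference (ms), <= 300.
#' @param n_saccades number of saccadic step deflections during alert periods.
#' @param saccade_amp_range saccade amplitude range (uV).
#' @param alpha_freq_range alpha rhythm frequency range (Hz).
#' @param alpha_amp_uv alpha burst peak amplitude (uV).
#' @param alpha_attenuation_factor multiplier applied to the alpha amplitude
#'   inside SEM intervals (alpha attenuates as sleep onset approaches).
#' @param drift_amp_uv slow baseline drift amplitude (uV).
#' @param drift_freq_hz drift frequency (Hz), below 0.1.
#' @param eeg_bg_sd_uv standard deviation of the pink (1/f) EEG background
#'   common to both EOG electrodes (uV).
#' @param noise_sd_uv per-channel independent sensor noise SD (uV).
#' @param seed integer RNG seed; identical seeds give bit-identical recordings.
#' @return validated configuration list of class `SimConfig`.
#' @export
simConfig <- function(duration_s = 400, fs = 500,
                      n_sem_events = 14,
                      sem_freq_range = c(0.2, 0.6),
                      sem_amp_range = c(30, 150),
                      sem_duration_range = c(3, 7),
                      onset_diff_max_ms = 150,
                      n_saccades = 30,
                      saccade_amp_range = c(50, 200),
                      alpha_freq_range = c(8, 13),
                      alpha_amp_uv = 35,
                      alpha_attenuation_factor = 0.3,
                      drift_amp_uv = 15,
                      drift_freq_hz = 0.05,
                      eeg_bg_sd_uv = 5,
                      noise_sd_uv = 3,
                      seed = 1L) {
  stopIfNot(is.numeric(fs) && fs > 0, "fs must be positive")
  stopIfNot(duration_s > 0, "duration_s must be positive")
  checkRange(sem_freq_range, "sem_freq_range", 0.2, 0.6)
  checkRange(sem_amp_range, "sem_amp_range", 20, 200)
  checkRange(sem_duration_range, "sem_duration_range")
  stopIfNot(sem_duration_range[1] > 2,
            "sem_duration_range lower bound must exceed 2 s (SEM duration criterion)")
  stopIfNot(onset_diff_max_ms >= 0 && onset_diff_max_ms <= 300,
            "onset_diff_max_ms must lie in [0, 300] (onset-difference criterion)")
  checkRange(saccade_amp_range, "saccade_amp_range", 0)
  checkRange(alpha_freq_range, "alpha_freq_range", 0)
  stopIfNot(alpha_attenuation_factor >= 0 && alpha_attenuation_factor <= 1,
            "alpha_attenuation_factor must lie in [0, 1]")
  stopIfNot(drift_freq_hz < 0.1, "drift_freq_hz must be below 0.1 Hz")
  cfg <- list(duration_s = duration_s, fs = fs, n_sem_events = n_sem_events,
              sem_freq_range = sem_freq_range, sem_amp_range = sem_amp_range,
              sem_duration_range = sem_duration_range,
              onset_diff_max_ms = onset_diff_max_ms,
              n_saccades = n_saccades, saccade_amp_range = saccade_amp_range,
              alpha_freq_range = alpha_freq_range, alpha_amp_uv = alpha_amp_uv,
              alpha_attenuation_factor = alpha_attenuation_factor,
              drift_amp_uv = drift_amp_uv, drift_freq_hz = drift_freq_hz,
              eeg_bg_sd_uv = eeg_bg_sd_uv, noise_sd_uv = noise_sd_uv,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# raised-cosine (Tukey) taper over the first/last `frac` of an event; keeps
# the onset well defined while avoiding step artifacts above 1 Hz
tukeyTaper <- function(n, frac = 0.1) {
  w <- rep(1, n)
  m <- max(1L, round(frac * n))
  ramp <- 0.5 * (1 - cos(pi * seq_len(m) / m))
  w[seq_len(m)] <- ramp
  w[n + 1 - seq_len(m)] <- ramp
  w
}

#' Generate one slow-eye-movement event
#'
#' Opposite-phase slow sinusoidal excursions on the two horizontal EOG
#' channels: the left-canthus component is a Tukey-tapered sinusoid, the
#' right-canthus component its negation delayed by the onset difference.
#' Parameters outside the visual labeling criteria are rejected.
#'
#' @param freq sinusoid frequency in Hz, within [0.2, 0.6].
#' @param amp peak amplitude in uV, within [20, 200].
#' @param duration event duration in seconds, > 2.
#' @param onset_diff inter-channel onset difference in ms, <= 300.
#' @param fs sampling rate in Hz.
#' @return list with components `hl`, `hr` (numeric vectors over the event
#'   support, zero outside it) and `n` (support length in samples).
#' @examples
#' ev <- generateSemEvent(0.4, 100, 3, 0, fs = 500)
#' max(abs(ev$hl + ev$hr))  # exact opposite phase when onset_diff = 0
#' @export
generateSemEvent <- function(freq, amp, duration, onset_diff = 0, fs = 500) {
  stopIfNot(freq >= 0.2 && freq <= 0.6,
            "frequency criterion violated: freq must lie in [0.2, 0.6] Hz")
  stopIfNot(amp >= 20 && amp <= 200,
            "amplitude criterion violated: amp must lie in [20, 200] uV")
  stopIfNot(duration > 2,
            "duration criterion violated: duration must exceed 2 s")
  stopIfNot(onset_diff >= 0 && onset_diff <= 300,
            "onset-difference criterion violated: onset_diff must be <= 300 ms")
  nd <- round(duration * fs)
  shift <- round(onset_diff / 1000 * fs)
  n <- nd + shift
  t <- (seq_len(nd) - 1) / fs
  s <- amp * sin(2 * pi * freq * t) * tukeyTaper(nd)
  hl <- c(s, rep(0, shift))
  hr <- c(rep(0, shift), -s)
  list(hl = hl, hr = hr, n = n)
}

#' Generate one saccadic deflection
#'
#' Step-like opposite-phase deflection with a linear rise to a sustained
#' plateau, as seen on horizontal EOG during alert, eyes-open periods. Unlike
#' SEM, its energy is concentrated at the step edge (well above the SEM
#' band), so it must fail the SEM frequency criterion.
#'
#' @param amp plateau amplitude in uV (>= 0; zero yields all-zero traces).
#' @param rise_ms linear rise time in ms.
#' @param fs sampling rate in Hz.
#' @param plateau_s plateau duration in seconds.
#' @return list with components `hl`, `hr`, `n` as in [generateSemEvent()].
#' @export
generateSaccade <- function(amp, rise_ms = 20, fs = 500, plateau_s = 0.5) {
  stopIfNot(is.numeric(amp) && length(amp) == 1 && amp >= 0,
            "saccade amplitude must be non-negative")
  stopIfNot(rise_ms > 0 && rise_ms < 1000, "rise_ms must lie in (0, 1000)")
  nr <- max(1L, round(rise_ms / 1000 * fs))
  np <- round(plateau_s * fs)
  s <- c(amp * seq_len(nr) / nr, rep(amp, np))
  list(hl = s, hr = -s, n = nr + np)
}

# band-limited pink (1/f) noise via spectral shaping, SD-normalized
pinkNoise <- function(n, fs, sd_uv, band = c(0.1, 30)) {
  if (sd_uv <= 0) return(rep(0, n))
  m <- 2^ceiling(log2(n))
  f <- seq(0, fs / 2, length.out = m / 2 + 1)
  mag <- ifelse(f >= band[1] & f <= band[2], 1 / sqrt(pmax(f, band[1])), 0)
  ph <- runif(m / 2 + 1, 0, 2 * pi)
  spec <- mag * exp(1i * ph)
  full <- c(spec, Conj(rev(spec[2:(m / 2)])))
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x * sd_uv / s else x
}

# smooth non-negative burst envelope with mean ~0.5, range [0, 1]
burstEnvelope <- function(n, fs, burst_hz = 0.8) {
  m <- 2^ceiling(log2(n))
  raw <- rnorm(m)
  f <- seq(0, fs / 2, length.out = m / 2 + 1)
  H <- exp(-(f / burst_hz)^2)
  spec <- fft(raw) * c(H, rev(H[2:(m / 2)]))
  sm <- Re(fft(spec, inverse = TRUE)) / m
  sm <- sm[seq_len(n)]
  env <- sm - min(sm)
  if (max(env) > 0) env <- env / max(env)
  env
}

placeIntervals <- function(duration_s, lengths_s, guard_s = 1,
                           avoid = NULL, max_attempts = 1000) {
  placed <- if (is.null(avoid)) data.frame(start = numeric(0), end = numeric(0))
            else data.frame(start = avoid$start, end = avoid$end)
  out <- data.frame(start = numeric(0), end = numeric(0))
  for (len in lengths_s) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      st <- runif(1, guard_s, duration_s - len - guard_s)
      en <- st + len
      if (!nrow(placed) ||
          all(en + guard_s <= placed$start | st - guard_s >= placed$end)) {
        placed <- rbind(placed, data.frame(start = st, end = en))
        out <- rbind(out, data.frame(start = st, end = en))
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not place %d non-overlapping events of total ",
                          "length %.1f s in %.1f s (placed %d)"),
                   length(lengths_s), sum(lengths_s), duration_s, nrow(out)),
           call. = FALSE)
  }
  out
}

#' Simulate a bimodal EOG/EEG recording with ground-truth SEM intervals
#'
#' Composes the left/right horizontal EOG channels and an occipital EEG
#' channel as
#' \deqn{Hl = +eye + EEG_{cm} + drift + noise, \quad
#'       Hr = -eye + EEG_{cm} + drift + noise,}
#' where `eye` collects SEM excursions and saccades, and the common-mode EEG
#' is pink background noise plus alpha bursts whose amplitude is multiplied
#' by the attenuation factor inside SEM intervals. `O2` shares the alpha
#' burst waveform of the common-mode EEG but has independent background and
#' sensor noise. By construction `Hl - Hr` isolates eye movement and
#' `Hl + Hr` isolates the EEG-like common mode.
#'
#' @param config a [simConfig()] list.
#' @return a [SemRecording-class] with channels `Hl`, `Hr`, `O2`, ground
#'   truth SEM/non-SEM intervals, and per-event parameters.
#' @export
simulateRecording <- function(config) {
  stopIfNot(inherits(config, "SimConfig"), "config must come from simConfig()")
  withSeed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs

    # --- SEM events -------------------------------------------------------
    nev <- config$n_sem_events
    evFreq <- runif(nev, config$sem_freq_range[1], config$sem_freq_range[2])
    evAmp <- runif(nev, config$sem_amp_range[1], config$sem_amp_range[2])
    evDur <- runif(nev, config$sem_duration_range[1], config$sem_duration_range[2])
    evOnset <- runif(nev, 0, config$onset_diff_max_ms)
    evLen <- evDur + evOnset / 1000
    sem <- if (nev > 0) placeIntervals(config$duration_s, evLen)
           else data.frame(start = numeric(0), end = numeric(0))

    eyeHl <- rep(0, n)
    eyeHr <- rep(0, n)
    if (nev > 0) {
      for (i in seq_len(nev)) {
        ev <- generateSemEvent(evFreq[i], evAmp[i], evDur[i], evOnset[i], fs)
        i0 <- round(sem$start[i] * fs)
        idx <- i0 + seq_len(ev$n)
        eyeHl[idx] <- eyeHl[idx] + ev$hl
        eyeHr[idx] <- eyeHr[idx] + ev$hr
        sem$end[i] <- (i0 + ev$n) / fs  # snap to sample grid
        sem$start[i] <- i0 / fs
      }
    }

    # --- saccades in alert (non-SEM) periods ------------------------------
    nsac <- config$n_saccades
    if (nsac > 0) {
      sacAmp <- runif(nsac, config$saccade_amp_range[1], config$saccade_amp_range[2])
      sacLen <- rep(2 * (0.02 + 0.5) + 0.02, nsac)  # up + mirrored return
      sac <- placeIntervals(config$duration_s, sacLen, guard_s = 1, avoid = sem)
      for (i in seq_len(nsac)) {
        sc <- generateSaccade(sacAmp[i], rise_ms = 20, fs = fs, plateau_s = 0.5)
        shape <- c(sc$hl, rev(sc$hl))  # gaze excursion returning to baseline
        i0 <- round(sac$start[i] * fs)
        idx <- i0 + seq_along(shape)
        keep <- idx <= n
        eyeHl[idx[keep]] <- eyeHl[idx[keep]] + shape[keep]
        eyeHr[idx[keep]] <- eyeHr[idx[keep]] - shape[keep]
      }
    }

    # --- EEG common mode: pink background + alpha bursts ------------------
    alphaFreq <- runif(1, config$alpha_freq_range[1], config$alpha_freq_range[2])
    env <- burstEnvelope(n, fs)
    atten <- rep(1, n)
    if (nrow(sem)) {
      for (i in seq_len(nrow(sem))) {
        idx <- which(t >= sem$start[i] & t < sem$end[i])
        atten[idx] <- config$alpha_attenuation_factor
      }
    }
    alpha <- config$alpha_amp_uv * env * atten *
      sin(2 * pi * alphaFreq * t + runif(1, 0, 2 * pi))
    commonEeg <- pinkNoise(n, fs, config$eeg_bg_sd_uv) + alpha

    drift <- config$drift_amp_uv *
      sin(2 * pi * config$drift_freq_hz * t + runif(1, 0, 2 * pi))

    hl <- eyeHl + commonEeg + drift + rnorm(n, 0, config$noise_sd_uv)
    hr <- eyeHr + commonEeg + drift + rnorm(n, 0, config$noise_sd_uv)
    o2 <- pinkNoise(n, fs, config$eeg_bg_sd_uv) + alpha + drift +
      rnorm(n, 0, config$noise_sd_uv)

    # --- ground truth: SEM intervals plus complement as non-SEM -----------
    ord <- order(sem$start)
    sem <- sem[ord, , drop = FALSE]
    evFreq <- evFreq[ord]; evAmp <- evAmp[ord]
    evDur <- evDur[ord]; evOnset <- evOnset[ord]
    iv <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     label = character(0), stringsAsFactors = FALSE)
    cursor <- 0
    if (nrow(sem)) {
      for (i in seq_len(nrow(sem))) {
        if (sem$start[i] > cursor)
          iv <- rbind(iv, data.frame(start_s = cursor, end_s = sem$start[i],
                                     label = "NONSEM"))
        iv <- rbind(iv, data.frame(start_s = sem$start[i], end_s = sem$end[i],
                                   label = "SEM"))
        cursor <- sem$end[i]
      }
    }
    if (cursor < config$duration_s)
      iv <- rbind(iv, data.frame(start_s = cursor, end_s = config$duration_s,
                                 label = "NONSEM"))

    ep <- if (nev > 0)
      data.frame(start_s = sem$start, end_s = sem$end, freq_hz = evFreq,
                 amp_uv = evAmp, duration_s = evDur, onset_diff_ms = evOnset)
    else data.frame()

    sig <- cbind(Hl = hl, Hr = hr, O2 = o2)
    methods::new("SemRecording", signals = sig, fs = fs,
                 subjectId = sprintf("SIM%02d", config$seed %% 100),
                 intervals = iv, eventParams = ep)
  })
}
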