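#' Pink background noise
#'
#' Generates 1/f ("pink") noise by spectral shaping of white Gaussian
#' noise: the one-sided power spectral density is `c/f` above 1 Hz and
#' flat below 1 Hz, with `c = rms^2 / ln(100)` so that the expected RMS
#' over the 1-100 Hz band equals `rms`. Uses the current RNG state.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param rms target RMS over the 1-100 Hz band (uV).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, rms = 10) {
  if (rms == 0) return(numeric(n))
  # FFT on a 5-smooth length (stats::fft degrades to O(m^2) at large
  # prime lengths); the stationary series is then truncated to n.
  m <- stats::nextn(n, c(2, 3, 5))
  c0 <- rms^2 / log(100)
  f <- (0:(m - 1)) * fs / m
  fmir <- pmin(f, fs - f)            # two-sided frequency magnitude
  S <- c0 / pmax(fmir, 1)            # flat below 1 Hz
  S[1] <- 0                          # no DC
  H <- sqrt(S * fs / 2)
  W <- stats::fft(stats::rnorm(m))
  (Re(stats::fft(W * H, inverse = TRUE)) / m)[seq_len(n)]
}

#' One-sided density of the pink-noise model
#'
#' The analytic spectral density of [pink_noise()] at frequency `f`:
#' `c / max(f, 1)` with `c = rms^2 / ln(100)`. Used as the analytic
#' noise term when predicting narrowband SNR of generated sessions.
#'
#' @param rms target band RMS (uV).
#' @param f frequency or frequencies (Hz).
#' @return Density in uV^2/Hz.
#' @export
pink_noise_density <- function(rms, f) (rms^2 / log(100)) / pmax(f, 1)

#' Symmetric square wave
#'
#' Phase-defined square wave with an exact 50% duty cycle (so that even
#' harmonics vanish identically, as for an ideal function generator).
#'
#' @param t time vector (s).
#' @param f0 fundamental frequency (Hz).
#' @param amplitude peak amplitude (the wave alternates +/- amplitude).
#' @param phase phase offset in cycles.
#' @return Numeric vector.
#' @export
square_wave <- function(t, f0, amplitude = 1, phase = 0) {
  amplitude * ifelse(((f0 * t + phase) %% 1) < 0.5, 1, -1)
}

#' Evoked-response template as a sum of Gaussians
#'
#' @param t time vector relative to stimulus onset (s).
#' @param components named list of numeric `c(latency, width, amplitude)`
#'   triplets (s, s, uV), e.g.
#'   `list(N1 = c(0.1, 0.025, -5), P2 = c(0.2, 0.04, 3.9))`.
#' @return Numeric vector, sum of the component Gaussians.
#' @export
erp_template <- function(t, components) {
  out <- numeric(length(t))
  for (cmp in components)
    out <- out + cmp[3] * exp(-((t - cmp[1])^2) / (2 * cmp[2]^2))
  out
}

# Smooth saccade step: rises around 50 ms, holds through the assessment
# time (200 ms), returns around 450 ms.
saccade_shape <- function(t) {
  stats::plogis((t - 0.05) / 0.015) - stats::plogis((t - 0.45) / 0.03)
}

# Blink bump with a shallow undershoot; unit-free shape, rescaled to a
# target peak-to-peak amplitude at generation time.
blink_shape <- function(t) {
  exp(-((t - 0.2)^2) / (2 * 0.05^2)) - 0.25 * exp(-((t - 0.45)^2) / (2 * 0.08^2))
}

default_erp_components_for <- function(paradigm) {
  switch(paradigm,
    aep = list(P1 = c(0.05, 0.015, 2), N1 = c(0.10, 0.025, -5),
               P2 = c(0.20, 0.040, 3.9)),
    vep = list(N1 = c(0.10, 0.020, -3), P2 = c(0.20, 0.040, 15)),
    aep_oddball = list(P1 = c(0.05, 0.015, 1.5), N1 = c(0.10, 0.025, -4),
                       P2 = c(0.20, 0.040, 3)),
    vep_oddball = list(N1 = c(0.10, 0.020, -2), P2 = c(0.22, 0.040, 4)),
    list())
}

default_deviant_delta_for <- function(paradigm) {
  switch(paradigm,
    aep_oddball = list(MMN = c(0.20, 0.035, -2)),
    vep_oddball = list(P300 = c(0.28, 0.050, 6)),
    list())
}

# Bench trigger latencies: auditory chain 0 ms, visual chain 21 ms,
# with their measured jitters. These are per-system quantities; the
# generator uses them as defaults and analyses correct for the means.
default_latency_for <- function(paradigm) {
  if (paradigm %in% c("vep", "vep_oddball", "ssvep", "eog"))
    c(mean = 0.021, jitter = 0.0028)
  else if (paradigm %in% c("aep", "aep_oddball", "assr"))
    c(mean = 0, jitter = 0.0022)
  else c(mean = 0, jitter = 0)
}

#' Ground-truth effect specification for the session generator
#'
#' Collects every injected effect parameter with defaults chosen to
#' emulate the magnitudes reported for scalp recordings: a 30 uV
#' eyes-closed alpha rhythm suppressed 4x in power when the eyes open,
#' steady-state amplitudes around 1.5 uV over a 10 uVrms pink-noise
#' floor, classic Gaussian-sum ERP templates (N1-P2 peak-to-peak
#' 8.9 uV for the auditory response, 15 uV visual P2), 8 mV / 1.5 mV
#' hard/soft blinks, and 10 uV / 2 uV horizontal/vertical saccade
#' separations. Ear channels receive cortical signals attenuated to
#' 0.3x scalp gain and ocular signals at 1.5x (proximity emulation
#' constants).
#'
#' @param noise_rms pink-noise RMS over 1-100 Hz, per channel (uV).
#' @param line_amp amplitude of an optional 50 Hz line component (uV).
#' @param alpha_freq,alpha_amp,alpha_ratio alpha rhythm frequency (Hz),
#'   eyes-closed amplitude (uV), and closed/open power ratio.
#' @param assr_freq,assr_amp steady-state auditory response frequency
#'   and amplitude.
#' @param ssvep_freq,ssvep_amp,ssvep_harmonic_decay,ssvep_max_harmonic
#'   SSVEP fundamental, amplitude, per-harmonic amplitude decay factor
#'   and number of harmonics.
#' @param erp_components,deviant_delta Gaussian-sum templates (see
#'   [erp_template()]); `NULL` selects the per-paradigm default.
#' @param blink_p2p_hard,blink_p2p_soft blink peak-to-peak amplitudes
#'   at frontal channels (uV).
#' @param saccade_amp_horizontal,saccade_amp_vertical half-separation
#'   step amplitudes (uV).
#' @param cortical_ear_gain,eog_ear_gain ear-channel gains relative to
#'   scalp for cortical and ocular signals.
#' @param latency_mean,latency_jitter trigger latency of the stimulus
#'   chain (s); `NULL` selects the per-paradigm bench default.
#' @return An object of class `effect_spec` (a named list).
#' @export
effect_spec <- function(noise_rms = 10, line_amp = 0,
                        alpha_freq = 10, alpha_amp = 30, alpha_ratio = 4,
                        assr_freq = 40, assr_amp = 1.5,
                        ssvep_freq = 10, ssvep_amp = 1.5,
                        ssvep_harmonic_decay = 0.5, ssvep_max_harmonic = 5,
                        erp_components = NULL, deviant_delta = NULL,
                        blink_p2p_hard = 8000, blink_p2p_soft = 1500,
                        saccade_amp_horizontal = 5, saccade_amp_vertical = 1,
                        cortical_ear_gain = 0.3, eog_ear_gain = 1.5,
                        latency_mean = NULL, latency_jitter = NULL) {
  stopifnot(noise_rms >= 0, alpha_amp >= 0, assr_amp >= 0, ssvep_amp >= 0,
            alpha_ratio > 0, blink_p2p_hard >= 0, blink_p2p_soft > 0,
            cortical_ear_gain >= 0, eog_ear_gain >= 0)
  structure(as.list(environment()), class = "effect_spec")
}

paradigm_defaults <- function(paradigm) {
  switch(paradigm,
    resting     = list(duration_s = 240),
    alpha_block = list(duration_s = 240, block_s = 60),
    assr        = list(duration_s = 240),
    ssvep       = list(duration_s = 240),
    aep         = list(n_trials = 200, stimulus_duration_s = 0.2,
                       isi = c(1.2, 1.8)),
    vep         = list(n_trials = 200, stimulus_duration_s = 0.5,
                       isi = c(0.5, 0.5)),
    aep_oddball = list(n_trials = 200, stimulus_duration_s = 0.1,
                       isi = c(1.2, 1.8)),
    vep_oddball = list(n_trials = 200, stimulus_duration_s = 0.5,
                       isi = c(0.6, 0.7)),
    eog         = list(n_trials = 80, stimulus_duration_s = 0.5,
                       isi = c(1.0, 1.6), n_blinks = 20,
                       blink_isi = c(3.5, 4.5)),
    stop("unknown paradigm: ", paradigm, call. = FALSE))
}

#' Session specification for the synthetic generator
#'
#' Encodes one paradigm session: trial counts, stimulus durations and
#' inter-stimulus-interval laws follow the acquisition battery
#' (4-minute continuous blocks for resting/alpha/ASSR/SSVEP; 200 trials
#' with the stated stimulus durations and uniform ISIs for the
#' transient and oddball paradigms; 80 dot-movement trials plus cued
#' blink blocks for EOG), at 500 Hz on the 12-channel scalp plus
#' 2 x 8 ear montage.
#'
#' @param paradigm one of `"resting"`, `"alpha_block"`, `"assr"`,
#'   `"ssvep"`, `"aep"`, `"vep"`, `"aep_oddball"`, `"vep_oddball"`,
#'   `"eog"`.
#' @param fs sampling rate (Hz, default 500).
#' @param montage an [montage()] (default [default_montage()]).
#' @param n_trials,duration_s,stimulus_duration_s,isi,block_s overrides
#'   of the per-paradigm defaults (`isi` is a `(min, max)` uniform law
#'   on the stimulus-offset-to-next-onset gap, in seconds).
#' @param oddball_fraction deviant probability for oddball paradigms
#'   (default 0.2, with no two consecutive deviants).
#' @param effect an [effect_spec()].
#' @param seed integer RNG seed; sessions are bit-reproducible given
#'   the spec.
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(paradigm, fs = 500, montage = default_montage(),
                         n_trials = NULL, duration_s = NULL,
                         stimulus_duration_s = NULL, isi = NULL,
                         block_s = NULL, oddball_fraction = 0.2,
                         effect = effect_spec(), seed = 1L) {
  defs <- paradigm_defaults(paradigm)
  spec <- list(paradigm = paradigm, fs = fs, montage = montage,
               n_trials = n_trials %||% defs$n_trials,
               duration_s = duration_s %||% defs$duration_s,
               stimulus_duration_s = stimulus_duration_s %||%
                 defs$stimulus_duration_s,
               isi = isi %||% defs$isi,
               block_s = block_s %||% defs$block_s,
               n_blinks = defs$n_blinks, blink_isi = defs$blink_isi,
               oddball_fraction = oddball_fraction,
               effect = effect, seed = as.integer(seed))
  if (!is.null(spec$isi)) {
    if (spec$isi[1] < 0 || spec$isi[1] > spec$isi[2])
      stop("need 0 <= isi_min <= isi_max", call. = FALSE)
    if (spec$stimulus_duration_s + spec$isi[1] < 0.6)
      stop("inter-trial spacing shorter than the 0.6 s response template",
           call. = FALSE)
  }
  if (!(oddball_fraction > 0 && oddball_fraction < 1))
    stop("`oddball_fraction` must be in (0, 1)", call. = FALSE)
  structure(spec, class = "session_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalp topography weights for cortical signals: fronto-central
# maximum for auditory paradigms, occipito-parietal for visual and
# alpha. Non-degenerate across channels so that re-referencing leaves
# a (possibly inverted) residual response, as seen on real caps.
scalp_topography <- function(paradigm) {
  if (paradigm %in% c("aep", "aep_oddball", "assr"))
    c(F3 = 0.8, Fz = 0.9, F4 = 0.8, T7 = 0.5, C3 = 0.8, Cz = 1.0,
      C4 = 0.8, T8 = 0.5, P3 = 0.7, Pz = 0.8, P4 = 0.9, Oz = 0.4)
  else
    c(F3 = 0.2, Fz = 0.2, F4 = 0.2, T7 = 0.3, C3 = 0.4, Cz = 0.4,
      C4 = 0.4, T8 = 0.3, P3 = 0.7, Pz = 0.8, P4 = 0.7, Oz = 1.0)
}

# Per-channel gain vectors for signal injection.
cortical_gains <- function(m, effect, paradigm) {
  topo <- scalp_topography(paradigm)
  g <- c(ifelse(is.na(topo[m$scalp_labels]), 1, topo[m$scalp_labels]),
         rep(effect$cortical_ear_gain, length(m$ear_labels)))
  stats::setNames(g, montage_labels(m))
}

left_right_sign <- function(labels) {
  sgn <- rep(0, length(labels))
  sgn[grepl("^(F3|T7|C3|P3|EL)", labels)] <- 1
  sgn[grepl("^(F4|T8|C4|P4|ER)", labels)] <- -1
  sgn
}

eog_gains <- function(m, effect) {
  labels <- montage_labels(m)
  ear <- labels %in% m$ear_labels
  horiz <- left_right_sign(labels) * ifelse(ear, effect$eog_ear_gain, 1)
  vert <- ifelse(labels %in% c("F3", "Fz", "F4"), 1, 0.3) *
    ifelse(ear, effect$eog_ear_gain, 1)
  list(horizontal = stats::setNames(horiz, labels),
       vertical = stats::setNames(vert, labels))
}

# Accumulate a template into a single-row signal vector at an onset
# time; the vector is later broadcast across channels with one outer().
add_template <- function(sig, onset_rel_t0, fs, template_fun, span) {
  n <- length(sig)
  i0 <- floor(onset_rel_t0 * fs) + 1L        # first sample at/after onset
  idx <- i0:min(n, i0 + ceiling(span * fs))
  idx <- idx[idx >= 1]
  if (!length(idx)) return(sig)
  tt <- (idx - 1L) / fs - onset_rel_t0
  sig[idx] <- sig[idx] + template_fun(tt)
  sig
}

schedule_trials <- function(n_trials, stim_s, isi, lead_in) {
  onsets <- numeric(n_trials)
  t <- lead_in
  for (i in seq_len(n_trials)) {
    onsets[i] <- t
    t <- t + stim_s + stats::runif(1, isi[1], isi[2])
  }
  onsets
}

oddball_labels <- function(n, fraction, standard = "standard",
                           deviant = "deviant") {
  labels <- character(n)
  prev_dev <- TRUE                    # never start with a deviant
  for (i in seq_len(n)) {
    is_dev <- !prev_dev && stats::runif(1) < fraction
    labels[i] <- if (is_dev) deviant else standard
    prev_dev <- is_dev
  }
  labels
}

#' Generate a synthetic paradigm session
#'
#' Simulates one recording session with known ground truth: pink
#' background noise on every channel, the paradigm's effect injected
#' with per-channel gains, markers with the stimulus chain's trigger
#' latency and jitter applied between marker and physical onset.
#' Bit-reproducible for a fixed spec (including its seed).
#'
#' @param spec a [session_spec()].
#' @return A list with elements `recording` (an `eeg_recording`),
#'   `markers` (a `marker_stream`) and `truth` (a list recording every
#'   injected parameter: marker and physical onset times, trial
#'   labels, templates, expected narrowband SNR / alpha modulation
#'   where applicable).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(spec$seed)
  fs <- spec$fs
  m <- spec$montage
  labels <- montage_labels(m)
  nch <- length(labels)
  eff <- spec$effect
  lat <- if (is.null(eff$latency_mean))
    default_latency_for(spec$paradigm)
  else c(mean = eff$latency_mean,
         jitter = eff$latency_jitter %||% 0)
  lead_in <- 5; lead_out <- 5
  gains_c <- cortical_gains(m, eff, spec$paradigm)
  truth <- list(paradigm = spec$paradigm, seed = spec$seed, fs = fs,
                effect = unclass(eff), latency = lat,
                cortical_gains = gains_c)

  ev_time <- numeric(); ev_label <- character()
  trial_onsets <- NULL; trial_labels <- NULL

  if (spec$paradigm %in% c("aep", "vep", "aep_oddball", "vep_oddball", "eog")) {
    onsets <- schedule_trials(spec$n_trials, spec$stimulus_duration_s,
                              spec$isi, lead_in)
    trial_labels <- switch(spec$paradigm,
      aep = rep("stim", spec$n_trials),
      vep = rep("stim", spec$n_trials),
      aep_oddball = oddball_labels(spec$n_trials, spec$oddball_fraction),
      vep_oddball = oddball_labels(spec$n_trials, spec$oddball_fraction),
      eog = sample(rep(paste0("saccade_", c("up", "down", "left", "right")),
                       length.out = spec$n_trials)))
    if (spec$paradigm == "eog") {
      # cued blink blocks after the saccade block, slower pacing so the
      # 3 s analysis window holds a single blink
      t <- onsets[length(onsets)] + spec$stimulus_duration_s + 3
      blink_onsets <- numeric(2 * spec$n_blinks)
      for (i in seq_along(blink_onsets)) {
        blink_onsets[i] <- t
        t <- t + stats::runif(1, spec$blink_isi[1], spec$blink_isi[2])
      }
      blink_labels <- sample(rep(c("blink_hard", "blink_soft"),
                                 each = spec$n_blinks))
      onsets <- c(onsets, blink_onsets)
      trial_labels <- c(trial_labels, blink_labels)
    }
    delays <- lat["mean"] + lat["jitter"] * stats::rnorm(length(onsets))
    phys_onsets <- onsets + delays
    duration <- max(phys_onsets) + 3 + lead_out
    ev_time <- onsets; ev_label <- trial_labels
    trial_onsets <- phys_onsets
    truth$marker_times <- onsets
    truth$onset_times <- phys_onsets
    truth$labels <- trial_labels
  } else {
    duration <- spec$duration_s + lead_in + lead_out
  }

  n <- round(duration * fs)
  t_abs <- (seq_len(n) - 1) / fs
  data <- matrix(0, nch, n)
  for (i in seq_len(nch)) data[i, ] <- pink_noise(n, fs, eff$noise_rms)
  if (eff$line_amp > 0)
    data <- data + matrix(eff$line_amp * sin(2 * pi * 50 * t_abs),
                          nch, n, byrow = TRUE)

  if (spec$paradigm == "alpha_block") {
    n_blocks <- ceiling(spec$duration_s / spec$block_s)
    block_starts <- lead_in + (seq_len(n_blocks) - 1) * spec$block_s
    block_labels <- rep(c("eyes_open", "eyes_closed"),
                        length.out = n_blocks)
    amp_closed <- eff$alpha_amp
    amp_open <- eff$alpha_amp / sqrt(eff$alpha_ratio)
    env <- rep(0, n)
    for (b in seq_len(n_blocks)) {
      i1 <- floor(block_starts[b] * fs) + 1L
      i2 <- min(n, floor((block_starts[b] + spec$block_s) * fs))
      env[i1:i2] <- if (block_labels[b] == "eyes_closed") amp_closed
                    else amp_open
    }
    osc <- sin(2 * pi * eff$alpha_freq * t_abs)
    data <- data + outer(unname(gains_c), env * osc)
    ev_time <- block_starts; ev_label <- block_labels
    truth$block_starts <- block_starts
    truth$block_labels <- block_labels
    truth$amp_closed <- amp_closed
    truth$amp_open <- amp_open
    truth$expected_ram_db <- vapply(
      gains_c, function(g) expected_alpha_ram_db(
        amp_closed, amp_open, eff$noise_rms, fs = fs, channel_gain = g),
      numeric(1))
    truth$injected_ram_db <- 10 * log10(eff$alpha_ratio)
  } else if (spec$paradigm == "assr") {
    sig <- eff$assr_amp * sin(2 * pi * eff$assr_freq *
                                (t_abs - lead_in))
    sig[t_abs < lead_in | t_abs > lead_in + spec$duration_s] <- 0
    data <- data + outer(unname(gains_c), sig)
    ev_time <- c(lead_in, lead_in + spec$duration_s)
    ev_label <- c("assr_start", "assr_stop")
    truth$expected_snr_db <- vapply(
      gains_c, function(g) expected_snr_db(
        eff$assr_amp, eff$noise_rms, eff$assr_freq,
        c(eff$assr_freq - 5, eff$assr_freq + 5), fs = fs,
        channel_gain = g),
      numeric(1))
  } else if (spec$paradigm == "ssvep") {
    k_max <- min(eff$ssvep_max_harmonic,
                 floor((fs / 2 - 5) / eff$ssvep_freq))
    sig <- numeric(n)
    for (k in seq_len(k_max))
      sig <- sig + eff$ssvep_amp * eff$ssvep_harmonic_decay^(k - 1) *
        sin(2 * pi * k * eff$ssvep_freq * (t_abs - lead_in))
    sig[t_abs < lead_in | t_abs > lead_in + spec$duration_s] <- 0
    data <- data + outer(unname(gains_c), sig)
    ev_time <- c(lead_in, lead_in + spec$duration_s)
    ev_label <- c("ssvep_start", "ssvep_stop")
    truth$harmonic_amps <- eff$ssvep_amp *
      eff$ssvep_harmonic_decay^(seq_len(k_max) - 1)
    truth$expected_snr_db <- vapply(
      gains_c, function(g) expected_snr_db(
        eff$ssvep_amp, eff$noise_rms, eff$ssvep_freq,
        c(eff$ssvep_freq - 5, eff$ssvep_freq + 5), fs = fs,
        channel_gain = g),
      numeric(1))
  } else if (spec$paradigm %in% c("aep", "vep")) {
    cmps <- eff$erp_components %||% default_erp_components_for(spec$paradigm)
    sig <- numeric(n)
    for (on in trial_onsets)
      sig <- add_template(sig, on, fs,
                          function(tt) erp_template(tt, cmps), 0.6)
    data <- data + outer(unname(gains_c), sig)
    truth$template_components <- cmps
  } else if (spec$paradigm %in% c("aep_oddball", "vep_oddball")) {
    cmps <- eff$erp_components %||% default_erp_components_for(spec$paradigm)
    delta <- eff$deviant_delta %||% default_deviant_delta_for(spec$paradigm)
    sig <- numeric(n)
    for (k in seq_along(trial_onsets)) {
      tpl <- if (trial_labels[k] == "deviant")
        function(tt) erp_template(tt, cmps) + erp_template(tt, delta)
      else function(tt) erp_template(tt, cmps)
      sig <- add_template(sig, trial_onsets[k], fs, tpl, 0.6)
    }
    data <- data + outer(unname(gains_c), sig)
    truth$template_components <- cmps
    truth$deviant_delta <- delta
    truth$n_deviants <- sum(trial_labels == "deviant")
  } else if (spec$paradigm == "eog") {
    g <- eog_gains(m, eff)
    tt_blink <- seq(0, 0.8, by = 1 / fs)
    shape_p2p <- max(blink_shape(tt_blink)) - min(blink_shape(tt_blink))
    sig_h <- numeric(n)                # horizontal-polarity signals
    sig_v <- numeric(n)                # vertical/frontal signals
    for (k in seq_along(trial_onsets)) {
      lab <- trial_labels[k]; on <- trial_onsets[k]
      if (lab %in% c("saccade_left", "saccade_right")) {
        sgn <- if (lab == "saccade_left") 1 else -1
        sig_h <- add_template(sig_h, on, fs,
                              function(tt) sgn * eff$saccade_amp_horizontal *
                                saccade_shape(tt), 0.7)
      } else if (lab %in% c("saccade_up", "saccade_down")) {
        sgn <- if (lab == "saccade_up") 1 else -1
        sig_v <- add_template(sig_v, on, fs,
                              function(tt) sgn * eff$saccade_amp_vertical *
                                saccade_shape(tt), 0.7)
      } else {
        p2p <- if (lab == "blink_hard") eff$blink_p2p_hard
               else eff$blink_p2p_soft
        sig_v <- add_template(sig_v, on, fs,
                              function(tt) p2p / shape_p2p * blink_shape(tt),
                              0.9)
      }
    }
    data <- data + outer(unname(g$horizontal), sig_h) +
      outer(unname(g$vertical), sig_v)
    truth$gain_maps <- g
    truth$blink_ratio <- eff$blink_p2p_hard / eff$blink_p2p_soft
  } else if (spec$paradigm == "resting") {
    ev_time <- lead_in; ev_label <- "rest_start"
  }

  rec <- recording(data, fs = fs, channel_labels = labels, t0 = 0,
                   reference_label = "FCz")
  markers <- marker_stream(ev_time, ev_label)
  list(recording = rec, markers = markers, truth = truth)
}

#' Analytic narrowband SNR of a generated steady-state session
#'
#' Expected value of [narrowband_snr()] for a sinusoid of amplitude
#' `amp` (after channel gain) in pink noise of band RMS `noise_rms`,
#' for a Hann-windowed Welch estimate: the bin-aligned sinusoid
#' contributes `amp^2 * L / (3 fs)` at its bin and a quarter of that at
#' each adjacent bin; the noise contributes the model density
#' [pink_noise_density()] at every bin.
#'
#' @param amp sinusoid amplitude (uV).
#' @param noise_rms pink-noise band RMS (uV).
#' @param f0 target frequency (Hz).
#' @param band neighbor band (Hz).
#' @param window_s Welch window (s, default 8).
#' @param fs sampling rate (Hz, default 500).
#' @param channel_gain gain applied to the sinusoid (default 1).
#' @return Expected SNR in dB.
#' @export
expected_snr_db <- function(amp, noise_rms, f0, band, window_s = 8,
                            fs = 500, channel_gain = 1) {
  L <- round(window_s * fs)
  df <- 1 / window_s
  freqs <- (0:(L %/% 2)) * df
  ib <- which(freqs >= band[1] & freqs <= band[2])
  i0 <- ib[which.min(abs(freqs[ib] - f0))]
  nbr <- setdiff(ib, i0)
  a <- amp * channel_gain
  p_sig <- a^2 * L / (3 * fs)
  noise <- pink_noise_density(noise_rms, freqs)
  peak <- p_sig + noise[i0]
  leak <- numeric(length(freqs))
  for (j in c(i0 - 1L, i0 + 1L))
    if (j >= 1 && j <= length(freqs)) leak[j] <- p_sig / 4
  nb_mean <- mean(noise[nbr] + leak[nbr])
  10 * log10(peak / nb_mean)
}

#' Analytic alpha modulation of a generated alpha-block session
#'
#' Expected [alpha_modulation()] ratio when a bin-aligned alpha
#' sinusoid of amplitude `amp_closed` / `amp_open` rides on pink noise:
#' per condition, the mean band density is the sinusoid's total power
#' `amp^2/2` spread over the band bins plus the noise density averaged
#' over those bins.
#'
#' @param amp_closed,amp_open alpha amplitudes per condition (uV).
#' @param noise_rms pink-noise band RMS (uV).
#' @param alpha_band band (default `c(8, 12)` Hz).
#' @param window_s STFT window (s, default 2).
#' @param fs sampling rate (Hz, default 500).
#' @param channel_gain gain applied to the sinusoid (default 1).
#' @return Expected modulation in dB.
#' @export
expected_alpha_ram_db <- function(amp_closed, amp_open, noise_rms,
                                  alpha_band = c(8, 12), window_s = 2,
                                  fs = 500, channel_gain = 1) {
  df <- 1 / window_s
  freqs <- (0:(round(window_s * fs) %/% 2)) * df
  ib <- which(freqs >= alpha_band[1] & freqs <= alpha_band[2])
  width <- length(ib) * df
  noise_mean <- mean(pink_noise_density(noise_rms, freqs[ib]))
  dens <- function(a) (a * channel_gain)^2 / 2 / width + noise_mean
  10 * log10(dens(amp_closed) / dens(amp_open))
}

#' Generate a synthetic phantom playback recording
#'
#' Emulates the phantom bench: a square wave played through the
#' antennas, recorded at each ear electrode scaled by its contact
#' quality, with a contact-dependent noise floor (good contacts about
#' 1 uVrms; failed contacts hundreds of uVrms).
#'
#' @param square_amp_mV played-back square-wave amplitude (mV,
#'   default 100).
#' @param f0 playback frequency (Hz, default 10).
#' @param channel_labels electrode labels (default the 16 ear sensors).
#' @param contact_quality named character vector (`"good"`/`"bad"`) per
#'   electrode; unnamed electrodes default to `"good"`.
#' @param attenuation electrode-side amplitude relative to the played
#'   wave for a good contact (default 0.05). Each electrode's gain is
#'   additionally scaled by its position: sensors numbered 1-8 span
#'   0.5x to 1.5x, emulating increasing distance from the within-ear
#'   reference (canal electrodes see the strongest signal).
#' @param bad_gain_factor additional attenuation for a bad contact
#'   (default 0.1).
#' @param noise_floor_uvrms named numeric `c(good = ..., bad = ...)`
#'   noise RMS per contact class (default `c(good = 1, bad = 300)`).
#' @param duration_s recording length (s, default 20).
#' @param fs sampling rate (Hz, default 250).
#' @param seed RNG seed.
#' @return A list with `recording` and `truth` (per-channel gains,
#'   noise classes, `f0`).
#' @export
generate_phantom_recording <- function(square_amp_mV = 100, f0 = 10,
                                       channel_labels =
                                         default_montage()$ear_labels,
                                       contact_quality = NULL,
                                       attenuation = 0.05,
                                       bad_gain_factor = 0.1,
                                       noise_floor_uvrms =
                                         c(good = 1, bad = 300),
                                       duration_s = 20, fs = 250,
                                       seed = 1L) {
  stopifnot(square_amp_mV >= 0, all(noise_floor_uvrms >= 0))
  quality <- stats::setNames(rep("good", length(channel_labels)),
                             channel_labels)
  if (!is.null(contact_quality)) {
    unknown <- setdiff(names(contact_quality), channel_labels)
    if (length(unknown))
      stop("unknown channel label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    quality[names(contact_quality)] <- contact_quality
  }
  set.seed(seed)
  n <- round(duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  base <- square_wave(tt, f0, amplitude = square_amp_mV * 1000)
  data <- matrix(0, length(channel_labels), n)
  gains <- numeric(length(channel_labels))
  pos <- suppressWarnings(as.integer(sub("^\\D*", "", channel_labels)))
  pos_gain <- ifelse(is.na(pos), 1, 0.5 + (pmin(pos, 8) - 1) / 7)
  for (i in seq_along(channel_labels)) {
    g <- attenuation * pos_gain[i] *
      if (quality[i] == "bad") bad_gain_factor else 1
    gains[i] <- g
    nz <- noise_floor_uvrms[[quality[i]]]
    data[i, ] <- g * base + if (nz > 0) pink_noise(n, fs, nz) else 0
  }
  rec <- recording(data, fs = fs, channel_labels = channel_labels,
                   t0 = 0, reference_label = "Ex1")
  list(recording = rec,
       truth = list(f0 = f0, square_amp_mV = square_amp_mV,
                    gains = stats::setNames(gains, channel_labels),
                    quality = quality,
                    noise_floor_uvrms = noise_floor_uvrms, seed = seed))
}

#' Generate a synthetic trigger-latency bench recording
#'
#' Emulates the delay/jitter measurement: markers fire at scheduled
#' times and the physical stimulus trace steps on after a normally
#' distributed delay. Sampled fast (default 10 kHz) as a bench audio or
#' photo-diode capture would be.
#'
#' @param n_events number of marker/stimulus pairs (default 1000).
#' @param delay_mean,delay_jitter delay law in seconds (defaults the
#'   visual chain's 21 ms +/- 2.8 ms).
#' @param fs sampling rate (Hz, default 10000).
#' @param isi uniform gap between events (s, default `c(0.25, 0.35)`).
#' @param pulse_s stimulus pulse duration (s, default 0.05).
#' @param amplitude pulse amplitude (default 1).
#' @param seed RNG seed.
#' @return A list with `recording` (single channel `STIM`), `markers`
#'   and `truth` (`delays`, `delay_mean`, `delay_jitter`).
#' @export
generate_latency_recording <- function(n_events = 1000,
                                       delay_mean = 0.021,
                                       delay_jitter = 0.0028,
                                       fs = 10000, isi = c(0.25, 0.35),
                                       pulse_s = 0.05, amplitude = 1,
                                       seed = 1L) {
  set.seed(seed)
  gaps <- stats::runif(n_events, isi[1], isi[2])
  marker_t <- 1 + cumsum(c(0, gaps[-n_events]))
  delays <- delay_mean + delay_jitter * stats::rnorm(n_events)
  onsets <- marker_t + delays
  n <- round((max(onsets) + pulse_s + 1) * fs)
  x <- numeric(n)
  for (on in onsets) {
    i1 <- ceiling(on * fs) + 1L          # first sample at/after onset
    i2 <- min(n, floor((on + pulse_s) * fs) + 1L)
    if (i1 <= i2) x[i1:i2] <- amplitude
  }
  rec <- recording(matrix(x, 1), fs = fs, channel_labels = "STIM", t0 = 0)
  markers <- marker_stream(marker_t, rep("stim", n_events))
  list(recording = rec, markers = markers,
       truth = list(delays = delays, delay_mean = delay_mean,
                    delay_jitter = delay_jitter, seed = seed))
}

#' Write a full fixture suite to disk
#'
#' Generates one session per paradigm, a wet- and a dry-condition
#' phantom recording, and a trigger-latency bench case, writes each as
#' a session directory, and records all ground truth in
#' `manifest.json`. The manifest is byte-stable across runs with the
#' same seed.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base RNG seed; each fixture derives its own from it.
#' @param session_overrides named list of [session_spec()] overrides
#'   applied to every paradigm (e.g. `list(duration_s = 20)` for a
#'   quick smoke suite).
#' @param latency_overrides named list of
#'   [generate_latency_recording()] overrides.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L,
                               session_overrides = list(),
                               latency_overrides = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paradigms <- c("resting", "alpha_block", "assr", "ssvep", "aep", "vep",
                 "aep_oddball", "vep_oddball", "eog")
  manifest <- list(seed = seed, fixtures = list())
  for (i in seq_along(paradigms)) {
    p <- paradigms[i]
    args <- c(list(paradigm = p, seed = seed + i), session_overrides)
    ses <- generate_session(do.call(session_spec, args))
    write_recording(ses$recording, ses$markers, file.path(out_dir, p))
    manifest$fixtures[[p]] <- ses$truth
  }
  dry_quality <- stats::setNames(
    rep("bad", 4), c("ER3", "EL3", "EL7", "EL8"))
  ph_wet <- generate_phantom_recording(seed = seed + 100)
  ph_dry <- generate_phantom_recording(contact_quality = dry_quality,
                                       seed = seed + 101)
  write_recording(ph_wet$recording, marker_stream(),
                  file.path(out_dir, "phantom_wet"))
  write_recording(ph_dry$recording, marker_stream(),
                  file.path(out_dir, "phantom_dry"))
  manifest$fixtures$phantom_wet <- ph_wet$truth
  manifest$fixtures$phantom_dry <- ph_dry$truth
  lat <- do.call(generate_latency_recording,
                 c(list(seed = seed + 200), latency_overrides))
  write_recording(lat$recording, lat$markers,
                  file.path(out_dir, "latency"))
  manifest$fixtures$latency <- lat$truth
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
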