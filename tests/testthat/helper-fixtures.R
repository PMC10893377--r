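# Small in-code fixtures shared across test files.

# Recording with a pure sinusoid on each channel (amplitudes recycled).
sine_recording <- function(freqs, amps = 1, fs = 500, duration = 10,
                           labels = NULL) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  amps <- rep_len(amps, length(freqs))
  data <- t(vapply(seq_along(freqs),
                   function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                   numeric(n)))
  if (is.null(labels)) labels <- paste0("ch", seq_along(freqs))
  recording(data, fs = fs, channel_labels = labels)
}

# Hand-built PSD object with an explicit power row (for bin-arithmetic
# oracles that must not depend on welch_psd).
manual_psd <- function(freqs, power, label = "ch1", seg = NULL) {
  structure(
    list(freqs = freqs, power = matrix(power, nrow = 1),
         segment_power = seg,
         segment_count = if (is.null(seg)) 1L else dim(seg)[3],
         window_s = 1 / (freqs[2] - freqs[1]), overlap = 0.5,
         channel_labels = label),
    class = "eeg_psd")
}

# Epochs built directly from a trials x samples matrix (single channel).
manual_epochs <- function(trials, fs = 500, tmin = -0.1,
                          labels = NULL, channel = "ch1") {
  n_tr <- nrow(trials); n_s <- ncol(trials)
  dat <- array(0, dim = c(n_tr, 1, n_s))
  dat[, 1, ] <- trials
  structure(
    list(data = dat, fs = fs,
         times = tmin + (seq_len(n_s) - 1) / fs,
         window = c(tmin, tmin + (n_s - 1) / fs),
         event_labels = labels %||% rep("stim", n_tr),
         baseline_window = NULL, channel_labels = channel, n_dropped = 0L),
    class = "eeg_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Textbook one-way ANOVA on two groups, by the definitional formulas.
brute_anova <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  gm <- mean(c(g1, g2))
  ssb <- n1 * (mean(g1) - gm)^2 + n2 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(f = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}
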