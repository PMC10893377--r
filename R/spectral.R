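#' @noRd
hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)

# One-sided Hann periodograms of 50%-style overlapping segments.
# Returns freqs and a bins x segments matrix of densities (uV^2/Hz).
# Each segment is mean-removed before windowing.
segment_periodograms <- function(x, fs, L, overlap) {
  hop <- max(1L, round(L * (1 - overlap)))
  w <- hann_window(L)
  w2 <- sum(w^2)
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  nb <- L %/% 2L + 1L
  P <- matrix(0, nb, length(starts))
  for (j in seq_along(starts)) {
    xs <- x[starts[j]:(starts[j] + L - 1L)]
    xs <- xs - mean(xs)
    X <- stats::fft(xs * w)[1:nb]
    p <- Mod(X)^2 / (fs * w2)
    p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
    P[, j] <- p
  }
  list(freqs = (0:(nb - 1L)) * fs / L, P = P,
       seg_times = (starts - 1L) / fs + L / (2 * fs))
}

#' Welch power spectral density
#'
#' Averages one-sided Hann periodograms over overlapping segments
#' (defaults: 8 s window, 50% overlap, so the frequency resolution is
#' 0.125 Hz). Per-segment powers are retained for the spectral-peak
#' F-test.
#'
#' @param rec an `eeg_recording`.
#' @param window_s segment length in seconds (default 8).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return An object of class `eeg_psd`: `freqs` (Hz), `power`
#'   (channels x frequencies, uV^2/Hz), `segment_power`
#'   (channels x frequencies x segments), `segment_count`, `window_s`,
#'   `overlap`, `channel_labels`.
#' @export
welch_psd <- function(rec, window_s = 8, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(window_s * rec$fs)
  if (n_samples(rec) < L)
    stop("recording shorter than one Welch window (", window_s, " s)",
         call. = FALSE)
  nch <- n_channels(rec)
  first <- segment_periodograms(rec$data[1, ], rec$fs, L, overlap)
  nseg <- ncol(first$P)
  seg <- array(0, dim = c(nch, length(first$freqs), nseg))
  seg[1, , ] <- first$P
  if (nch > 1) for (i in 2:nch)
    seg[i, , ] <- segment_periodograms(rec$data[i, ], rec$fs, L, overlap)$P
  power <- apply(seg, c(1, 2), mean)
  structure(
    list(freqs = first$freqs, power = power, segment_power = seg,
         segment_count = nseg, window_s = window_s, overlap = overlap,
         channel_labels = rec$channel_labels),
    class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d channel(s), %d bins (df = %g Hz), %d segment(s) of %g s\n",
              nrow(x$power), length(x$freqs), x$freqs[2] - x$freqs[1],
              x$segment_count, x$window_s))
  invisible(x)
}

#' Short-time Fourier transform spectrogram
#'
#' Per-segment Hann periodograms on a sliding window (defaults: 2 s
#' window, 50% overlap, giving a 1 s hop and 0.5 Hz resolution).
#'
#' @inheritParams welch_psd
#' @param window_s segment length in seconds (default 2).
#' @return An object of class `eeg_spectrogram`: `times` (s, segment
#'   centres on the recording clock), `freqs` (Hz), `power`
#'   (channels x frequencies x frames, uV^2/Hz), `window_s`, `overlap`,
#'   `channel_labels`.
#' @export
stft_spectrogram <- function(rec, window_s = 2, overlap = 0.5) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(window_s * rec$fs)
  if (n_samples(rec) < L)
    stop("recording shorter than one STFT window (", window_s, " s)",
         call. = FALSE)
  nch <- n_channels(rec)
  first <- segment_periodograms(rec$data[1, ], rec$fs, L, overlap)
  pw <- array(0, dim = c(nch, length(first$freqs), ncol(first$P)))
  pw[1, , ] <- first$P
  if (nch > 1) for (i in 2:nch)
    pw[i, , ] <- segment_periodograms(rec$data[i, ], rec$fs, L, overlap)$P
  structure(
    list(times = rec$t0 + first$seg_times, freqs = first$freqs, power = pw,
         window_s = window_s, overlap = overlap,
         channel_labels = rec$channel_labels),
    class = "eeg_spectrogram")
}

#' @export
print.eeg_spectrogram <- function(x, ...) {
  cat(sprintf("<eeg_spectrogram> %d channel(s), %d bins x %d frames (%g s window)\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3], x$window_s))
  invisible(x)
}

psd_channel_index <- function(psd, channel) {
  i <- match(channel, psd$channel_labels)
  if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
  i
}

band_bins <- function(freqs, band) {
  which(freqs >= band[1] & freqs <= band[2])
}

# Core of the spectral-peak F-test: one-way ANOVA of log segment powers
# at the target bin vs the neighbor bins. Log transform stabilizes the
# variance of periodogram ordinates (approximately scaled chi-squared).
# Peaks below the double-precision dynamic range of the spectrum
# (1e-12 of the maximum mean power) are reported as non-detectable
# (F = 0, p = 1).
peak_ftest_core <- function(P, freqs, f0, band) {
  ib <- band_bins(freqs, band)
  if (!length(ib)) stop("band contains no frequency bins", call. = FALSE)
  i0 <- ib[which.min(abs(freqs[ib] - f0))]
  if (abs(freqs[i0] - f0) > (freqs[2] - freqs[1]))
    stop("f0 is not inside the band", call. = FALSE)
  nb <- setdiff(ib, i0)
  if (!length(nb)) stop("no neighbor bins in band", call. = FALSE)
  if (ncol(P) < 2) stop("need at least 2 segments for the F-test",
                        call. = FALSE)
  Pm <- rowMeans(P)
  floor_ <- 1e-12 * max(Pm)
  if (Pm[i0] <= floor_ || floor_ == 0)
    return(list(f_statistic = 0, p_value = 1, i0 = i0, neighbors = nb))
  gA <- log(P[i0, ] + floor_)
  gB <- log(as.vector(P[nb, ]) + floor_)
  va <- stats::var(gA); vb <- stats::var(gB)
  within <- ((length(gA) - 1) * va + (length(gB) - 1) * vb) /
    (length(gA) + length(gB) - 2)
  if (within < 1e-20) {
    if (abs(mean(gA) - mean(gB)) < 1e-10)
      return(list(f_statistic = 0, p_value = 1, i0 = i0, neighbors = nb))
    return(list(f_statistic = Inf, p_value = 0, i0 = i0, neighbors = nb))
  }
  v <- c(gA, gB)
  g <- factor(rep(c("f0", "nbr"), c(length(gA), length(gB))))
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(f_statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       i0 = i0, neighbors = nb)
}

#' F-test for a spectral peak
#'
#' One-way ANOVA comparing the per-segment Welch powers at the bin
#' nearest `f0` against the per-segment powers at the other bins of
#' `band`. Powers are log-transformed before the ANOVA to stabilize the
#' variance of the periodogram ordinates.
#'
#' @param psd an `eeg_psd` from [welch_psd()] (must retain segment
#'   powers).
#' @param channel channel label.
#' @param f0 target frequency (Hz).
#' @param band numeric length-2 band (Hz) containing `f0`.
#' @return A list with `f_statistic` and `p_value`.
#' @export
spectral_peak_ftest <- function(psd, channel, f0, band) {
  stopifnot(inherits(psd, "eeg_psd"))
  i <- psd_channel_index(psd, channel)
  P <- psd$segment_power[i, , , drop = TRUE]
  if (is.null(dim(P))) P <- matrix(P, ncol = psd$segment_count)
  r <- peak_ftest_core(P, psd$freqs, f0, band)
  list(f_statistic = r$f_statistic, p_value = r$p_value)
}

#' Narrowband signal-to-noise ratio
#'
#' The power at the bin nearest `f0` divided by the mean power over the
#' other bins of `band` (the target bin itself is excluded from the
#' average). This is the 40 Hz ASSR metric with `band = c(35, 45)` and
#' the 10 Hz SSVEP metric with `band = c(5, 15)`. When segment powers
#' are available, an F-test of the peak against its neighbors is run
#' and a significance flag is set (`p < alpha`, ratio above 1, peak
#' above the numerical detectability floor).
#'
#' @param psd an `eeg_psd`.
#' @param channel channel label.
#' @param f0 target frequency (Hz).
#' @param band numeric length-2 band (Hz) containing `f0`.
#' @param alpha significance level for the F-test (default 0.05).
#' @return An object of class `snr_result`: `channel`, `f0` (requested),
#'   `f0_bin` (Hz actually used), `band`, `snr_linear`, `snr_db`
#'   (`10*log10(snr_linear)`), `f_statistic`, `p_value`, `significant`,
#'   `n_neighbors`.
#' @export
narrowband_snr <- function(psd, channel, f0, band, alpha = 0.05) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (band[1] > f0 || band[2] < f0)
    stop("band must contain f0", call. = FALSE)
  i <- psd_channel_index(psd, channel)
  ib <- band_bins(psd$freqs, band)
  if (!length(ib)) stop("band outside the frequency grid", call. = FALSE)
  i0 <- ib[which.min(abs(psd$freqs[ib] - f0))]
  nbr <- setdiff(ib, i0)
  if (!length(nbr)) stop("no neighbor bins in band", call. = FALSE)
  p0 <- psd$power[i, i0]
  pn <- mean(psd$power[i, nbr])
  snr <- p0 / pn
  ft <- if (!is.null(psd$segment_power) && psd$segment_count >= 2) {
    P <- psd$segment_power[i, , , drop = TRUE]
    peak_ftest_core(P, psd$freqs, f0, band)
  } else list(f_statistic = NA_real_, p_value = NA_real_)
  detectable <- p0 > 1e-12 * max(psd$power[i, ])
  structure(
    list(channel = channel, f0 = f0, f0_bin = psd$freqs[i0], band = band,
         snr_linear = snr, snr_db = 10 * log10(snr),
         f_statistic = ft$f_statistic, p_value = ft$p_value,
         significant = isTRUE(!is.na(ft$p_value) && ft$p_value < alpha &&
                                snr > 1 && detectable),
         n_neighbors = length(nbr), alpha = alpha),
    class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> %s @ %g Hz: %.2f dB (F = %.3g, p = %.3g%s)\n",
              x$channel, x$f0, x$snr_db, x$f_statistic, x$p_value,
              if (x$significant) ", significant" else ""))
  invisible(x)
}

#' Harmonic scan of a spectrum
#'
#' Evaluates [narrowband_snr()] at every harmonic `k * fundamental` up
#' to `max_hz`, each with a +/- `neighbor_halfwidth` Hz neighbor band
#' clipped to the valid frequency range.
#'
#' @param psd an `eeg_psd`.
#' @param channel channel label.
#' @param fundamental fundamental frequency (Hz, > 0).
#' @param max_hz highest harmonic frequency to test.
#' @param neighbor_halfwidth half-width of the neighbor band (default 5 Hz).
#' @param alpha significance level (default 0.05).
#' @return A data.frame with one row per harmonic: `harmonic`, `f0`,
#'   `snr_linear`, `snr_db`, `f_statistic`, `p_value`, `significant`.
#' @export
harmonic_scan <- function(psd, channel, fundamental, max_hz,
                          neighbor_halfwidth = 5, alpha = 0.05) {
  stopifnot(inherits(psd, "eeg_psd"))
  if (fundamental <= 0) stop("`fundamental` must be positive", call. = FALSE)
  ks <- seq_len(floor(max_hz / fundamental))
  fmax <- max(psd$freqs)
  rows <- lapply(ks, function(k) {
    f0 <- k * fundamental
    band <- c(max(f0 - neighbor_halfwidth, psd$freqs[2]),
              min(f0 + neighbor_halfwidth, fmax))
    r <- narrowband_snr(psd, channel, f0, band, alpha = alpha)
    data.frame(harmonic = k, f0 = f0, snr_linear = r$snr_linear,
               snr_db = r$snr_db, f_statistic = r$f_statistic,
               p_value = r$p_value, significant = r$significant)
  })
  do.call(rbind, rows)
}

#' Local spectral peaks of a PSD
#'
#' Lists local maxima of the mean spectrum above a relative height
#' threshold, in ascending frequency order.
#'
#' @param psd an `eeg_psd`.
#' @param channel channel label.
#' @param min_rel_height minimum peak height as a fraction of the
#'   spectrum maximum (default 1e-4).
#' @return A data.frame with columns `freq` (Hz) and `power`, sorted by
#'   frequency.
#' @export
find_spectral_peaks <- function(psd, channel, min_rel_height = 1e-4) {
  stopifnot(inherits(psd, "eeg_psd"))
  i <- psd_channel_index(psd, channel)
  p <- psd$power[i, ]
  pk <- pracma::findpeaks(p, minpeakheight = max(p) * min_rel_height)
  if (is.null(pk)) return(data.frame(freq = numeric(), power = numeric()))
  ord <- order(pk[, 2])
  data.frame(freq = psd$freqs[pk[ord, 2]], power = pk[ord, 1])
}

mean_band_power <- function(power_bins) mean(power_bins)

#' Alpha-band modulation ratio from a spectrogram
#'
#' Quantifies alpha blocking as the ratio of the mean 8-12 Hz power
#' during eyes-closed intervals to the mean during eyes-open intervals,
#' reported both linear and in dB. Spectrogram frames are used only when
#' fully contained in a condition interval.
#'
#' @param spg an `eeg_spectrogram` from [stft_spectrogram()].
#' @param channel channel label.
#' @param closed_intervals,open_intervals lists of numeric length-2
#'   `(start, end)` times in seconds (recording clock) for the
#'   eyes-closed and eyes-open conditions.
#' @param alpha_band numeric length-2 band (default `c(8, 12)` Hz).
#' @return An object of class `alpha_modulation`: `ram_linear`,
#'   `ram_db`, `alpha_band`, `power_closed`, `power_open` (uV^2/Hz),
#'   `n_frames_closed`, `n_frames_open`.
#' @export
alpha_modulation <- function(spg, channel, closed_intervals, open_intervals,
                             alpha_band = c(8, 12)) {
  stopifnot(inherits(spg, "eeg_spectrogram"))
  if (!length(closed_intervals) || !length(open_intervals))
    stop("need at least one interval per condition", call. = FALSE)
  i <- match(channel, spg$channel_labels)
  if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
  fb <- band_bins(spg$freqs, alpha_band)
  if (!length(fb)) stop("alpha band outside the frequency grid", call. = FALSE)
  half <- spg$window_s / 2
  frames_in <- function(intervals) {
    sel <- rep(FALSE, length(spg$times))
    for (iv in intervals)
      sel <- sel | (spg$times - half >= iv[1] & spg$times + half <= iv[2])
    which(sel)
  }
  fc <- frames_in(closed_intervals)
  fo <- frames_in(open_intervals)
  if (!length(fc) || !length(fo))
    stop("a condition contains no complete spectrogram frames", call. = FALSE)
  pc <- mean(spg$power[i, fb, fc])
  po <- mean(spg$power[i, fb, fo])
  ram <- pc / po
  structure(
    list(ram_linear = ram, ram_db = 10 * log10(ram),
         alpha_band = alpha_band, power_closed = pc, power_open = po,
         n_frames_closed = length(fc), n_frames_open = length(fo)),
    class = "alpha_modulation")
}

#' Alpha-band modulation ratio from two PSDs
#'
#' Variant of [alpha_modulation()] for separately recorded or
#' pre-split conditions: the ratio of mean alpha-band Welch power of the
#' eyes-closed spectrum over the eyes-open spectrum.
#'
#' @param psd_closed,psd_open `eeg_psd` objects for the two conditions.
#' @param channel channel label (must exist in both).
#' @param alpha_band numeric length-2 band (default `c(8, 12)` Hz).
#' @return An `alpha_modulation` object.
#' @export
alpha_modulation_psd <- function(psd_closed, psd_open, channel,
                                 alpha_band = c(8, 12)) {
  stopifnot(inherits(psd_closed, "eeg_psd"), inherits(psd_open, "eeg_psd"))
  ic <- psd_channel_index(psd_closed, channel)
  io <- psd_channel_index(psd_open, channel)
  fbc <- band_bins(psd_closed$freqs, alpha_band)
  fbo <- band_bins(psd_open$freqs, alpha_band)
  if (!length(fbc) || !length(fbo))
    stop("alpha band outside the frequency grid", call. = FALSE)
  pc <- mean(psd_closed$power[ic, fbc])
  po <- mean(psd_open$power[io, fbo])
  ram <- pc / po
  structure(
    list(ram_linear = ram, ram_db = 10 * log10(ram),
         alpha_band = alpha_band, power_closed = pc, power_open = po,
         n_frames_closed = psd_closed$segment_count,
         n_frames_open = psd_open$segment_count),
    class = "alpha_modulation")
}

#' @export
print.alpha_modulation <- function(x, ...) {
  cat(sprintf("<alpha_modulation> %.2f dB (closed/open ratio %.3g, %g-%g Hz)\n",
              x$ram_db, x$ram_linear, x$alpha_band[1], x$alpha_band[2]))
  invisible(x)
}

#' Condition intervals from alternating block markers
#'
#' Builds per-condition time intervals from markers that announce block
#' starts (e.g. `"eyes_closed"` / `"eyes_open"`), discarding a settling
#' period after each transition. Each block extends to the next marker
#' or to `end_time`.
#'
#' @param markers a `marker_stream` on the recording clock.
#' @param labels character vector of block-start labels to use.
#' @param end_time end of the final block (s).
#' @param settle_s seconds discarded after each block start (default 2).
#' @return A named list, one element per label, each a list of
#'   `(start, end)` interval vectors.
#' @export
condition_intervals <- function(markers, labels, end_time, settle_s = 2) {
  ev <- markers$events
  t <- marker_times(markers)
  sel <- which(ev$label %in% labels)
  if (!length(sel)) stop("no block markers found", call. = FALSE)
  out <- stats::setNames(vector("list", length(labels)), labels)
  for (k in seq_along(sel)) {
    i <- sel[k]
    t_start <- t[i] + settle_s
    t_end <- if (k < length(sel)) t[sel[k + 1]] else end_time
    if (t_end > t_start)
      out[[ev$label[i]]] <- c(out[[ev$label[i]]], list(c(t_start, t_end)))
  }
  out
}
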