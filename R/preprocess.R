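#' Filter chain specification
#'
#' Defines the per-paradigm filtering chain: Butterworth high-pass, an
#' optional second-order IIR notch, then Butterworth low-pass, all
#' applied forward-backward (zero phase) by [apply_filter_chain()].
#'
#' @param highpass_hz high-pass corner (Hz).
#' @param lowpass_hz low-pass corner (Hz); must exceed `highpass_hz`.
#' @param notch_hz notch centre frequency (Hz), or `NULL` for none; must
#'   lie inside the passband when set.
#' @param order Butterworth order per pass (default 4).
#' @param notch_q quality factor of the notch (centre / -3 dB width;
#'   default 35).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(highpass_hz, lowpass_hz, notch_hz = NULL,
                        order = 4, notch_q = 35) {
  if (!(highpass_hz > 0) || !(lowpass_hz > highpass_hz))
    stop("need 0 < highpass_hz < lowpass_hz", call. = FALSE)
  if (!is.null(notch_hz) &&
      (notch_hz <= highpass_hz || notch_hz >= lowpass_hz))
    stop("`notch_hz` must lie inside (highpass_hz, lowpass_hz)", call. = FALSE)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 notch_hz = notch_hz, order = order, notch_q = notch_q),
            class = "filter_spec")
}

# RBJ-style second-order IIR notch coefficients (normalized a0 = 1).
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply a zero-phase filter chain to a recording
#'
#' Applies, in order: Butterworth high-pass, optional 2nd-order IIR
#' notch, Butterworth low-pass -- each forward-backward
#' (zero-phase, so effective attenuation is doubled and component
#' latencies are preserved).
#'
#' @param rec an `eeg_recording`.
#' @param spec a [filter_spec()] valid for `rec$fs` (all corners below
#'   the Nyquist frequency).
#' @return A filtered `eeg_recording` of the same shape.
#' @export
apply_filter_chain <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$lowpass_hz >= nyq ||
      (!is.null(spec$notch_hz) && spec$notch_hz >= nyq))
    stop("filter corner at or above the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  bh <- signal::butter(spec$order, spec$highpass_hz / nyq, type = "high")
  bl <- signal::butter(spec$order, spec$lowpass_hz / nyq, type = "low")
  nt <- if (!is.null(spec$notch_hz))
    notch_coefficients(spec$notch_hz, rec$fs, spec$notch_q)
  out <- rec$data
  for (i in seq_len(n_channels(rec))) {
    x <- signal::filtfilt(bh, rec$data[i, ])
    if (!is.null(nt)) x <- signal::filtfilt(signal::Arma(nt$b, nt$a), x)
    out[i, ] <- signal::filtfilt(bl, x)
  }
  rec$data <- out
  rec
}

#' Reference scheme
#'
#' @param kind `"channel"` (subtract a named channel) or `"none"` (leave
#'   the data as recorded).
#' @param channel_label reference channel label when `kind = "channel"`.
#' @return An object of class `reference_scheme`.
#' @export
reference_scheme <- function(kind = c("channel", "none"),
                             channel_label = NULL) {
  kind <- match.arg(kind)
  if (kind == "channel" && (is.null(channel_label) || !nzchar(channel_label)))
    stop("`channel_label` required for kind = \"channel\"", call. = FALSE)
  structure(list(kind = kind, channel_label = channel_label),
            class = "reference_scheme")
}

#' Re-reference a recording
#'
#' Subtracts the chosen reference channel from every channel (the
#' reference channel itself becomes identically zero) and updates
#' `reference_label`. Pairwise channel differences are preserved
#' exactly. A bare channel label may be given instead of a
#' [reference_scheme()].
#'
#' @param rec an `eeg_recording`.
#' @param scheme a [reference_scheme()] or a channel label string.
#' @return A re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, scheme) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(scheme))
    scheme <- reference_scheme("channel", scheme)
  stopifnot(inherits(scheme, "reference_scheme"))
  if (scheme$kind == "none") return(rec)
  i <- channel_index(rec, scheme$channel_label)
  rec$data <- rec$data - matrix(rec$data[i, ], nrow = n_channels(rec),
                                ncol = n_samples(rec), byrow = TRUE)
  rec$reference_label <- scheme$channel_label
  rec
}

round_half_up <- function(x) floor(x + 0.5)

#' Extract marker-locked epochs
#'
#' Cuts one trial per selected marker. The corrected onset time is the
#' marker time plus `latency_correction`, rounded to the nearest sample
#' (ties round up). Trials whose window would extend beyond the
#' recording are dropped and counted in `n_dropped`.
#'
#' @param rec an `eeg_recording`.
#' @param markers a `marker_stream` on the recording clock.
#' @param labels character vector of marker labels to epoch.
#' @param window numeric length-2 `(tmin, tmax)` in seconds relative to
#'   the corrected onset; must contain 0.
#' @param latency_correction constant added to marker times before
#'   rounding, in seconds (measured trigger latency of the stimulus
#'   chain; default 0).
#' @return An object of class `eeg_epochs`: `data`
#'   (trials x channels x samples array), `fs`, `times` (sample times
#'   relative to onset), `window`, `event_labels`, `baseline_window`
#'   (`NULL` until [baseline_correct()]), `channel_labels`, `n_dropped`.
#' @export
extract_epochs <- function(rec, markers, labels, window,
                           latency_correction = 0) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(markers, "marker_stream"))
  if (!(window[1] <= 0 && window[2] >= 0))
    stop("`window` must contain 0", call. = FALSE)
  ev <- markers$events
  sel <- which(ev$label %in% labels)
  if (!length(sel))
    stop("no markers matching label(s): ",
         paste(labels, collapse = ", "), call. = FALSE)
  fs <- rec$fs
  t_on <- marker_times(markers)[sel] + latency_correction
  i_on <- round_half_up((t_on - rec$t0) * fs) + 1L
  o_min <- round_half_up(window[1] * fs)
  n_samp <- round((window[2] - window[1]) * fs) + 1L
  offsets <- o_min + 0L:(n_samp - 1L)
  inside <- i_on + o_min >= 1L & i_on + offsets[n_samp] <= n_samples(rec)
  if (!any(inside))
    stop("all matching trials fall outside the recording", call. = FALSE)
  keep <- which(inside)
  dat <- array(NA_real_,
               dim = c(length(keep), n_channels(rec), n_samp))
  for (k in seq_along(keep))
    dat[k, , ] <- rec$data[, i_on[keep[k]] + offsets, drop = FALSE]
  structure(
    list(data = dat, fs = fs, times = offsets / fs, window = window,
         event_labels = ev$label[sel][keep],
         baseline_window = NULL,
         channel_labels = rec$channel_labels,
         n_dropped = sum(!inside)),
    class = "eeg_epochs")
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (typically the 100 ms pre-stimulus window).
#'
#' @param ep an `eeg_epochs` object.
#' @param baseline numeric length-2 `(t1, t2)` in seconds, contained in
#'   the epoch window.
#' @return The epochs with baseline removed and `baseline_window` set.
#' @export
baseline_correct <- function(ep, baseline = c(-0.1, 0)) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (baseline[1] < ep$window[1] || baseline[2] > ep$window[2])
    stop("baseline must lie within the epoch window", call. = FALSE)
  idx <- which(ep$times >= baseline[1] & ep$times <= baseline[2])
  if (!length(idx))
    stop("baseline interval contains no samples", call. = FALSE)
  bl <- apply(ep$data[, , idx, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim = dim(ep$data))
  ep$baseline_window <- baseline
  ep
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs))
  cat(sprintf("  window [%g, %g] s, baseline %s, dropped %d\n",
              x$window[1], x$window[2],
              if (is.null(x$baseline_window)) "none" else
                sprintf("[%g, %g] s", x$baseline_window[1], x$baseline_window[2]),
              x$n_dropped))
  invisible(x)
}

#' Number of trials in an epochs object
#' @param ep an `eeg_epochs` object.
#' @export
n_trials <- function(ep) dim(ep$data)[1]

#' Subset epochs by trial label
#'
#' @param ep an `eeg_epochs` object.
#' @param labels labels of trials to keep.
#' @return An `eeg_epochs` object with the matching trials.
#' @export
subset_epochs <- function(ep, labels) {
  keep <- which(ep$event_labels %in% labels)
  if (!length(keep)) stop("no trials with label(s): ",
                          paste(labels, collapse = ", "), call. = FALSE)
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$event_labels <- ep$event_labels[keep]
  ep
}
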