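#' Estimate trigger latency and jitter from a stimulus trace
#'
#' Measures the delay between software markers and the physical stimulus
#' they announce, from a bench recording of the stimulus itself (audio
#' line or photo-diode). For each marker, the trace is rectified within a
#' post-marker search window, and the onset is taken as the first
#' crossing of `onset_threshold` times the window maximum; the crossing
#' time is refined by linear interpolation between the samples
#' bracketing the threshold. Markers with no detectable onset in their
#' window are excluded and counted.
#'
#' @param stim_trace single-channel `eeg_recording` of the physical
#'   stimulus.
#' @param markers a `marker_stream` (timestamps on the recording clock).
#' @param onset_threshold fraction of the in-window maximum of the
#'   rectified trace that defines the onset (default 0.5).
#' @param search_window numeric length-2, post-marker search window in
#'   seconds (default `c(0, 0.2)`).
#' @return An object of class `latency_estimate`: `mean_delay` (s),
#'   `jitter` (s, standard deviation; 0 when a single event is usable),
#'   `n_events` (markers with a detected onset), `n_excluded`, and the
#'   per-event `delays`.
#' @export
estimate_marker_latency <- function(stim_trace, markers,
                                    onset_threshold = 0.5,
                                    search_window = c(0, 0.2)) {
  stopifnot(inherits(stim_trace, "eeg_recording"),
            inherits(markers, "marker_stream"))
  if (n_channels(stim_trace) != 1L)
    stop("`stim_trace` must have exactly one channel", call. = FALSE)
  if (nrow(markers$events) < 1L)
    stop("need at least one marker", call. = FALSE)
  if (!(onset_threshold > 0 && onset_threshold <= 1))
    stop("`onset_threshold` must be in (0, 1]", call. = FALSE)
  fs <- stim_trace$fs
  r <- abs(stim_trace$data[1, ])
  n <- length(r)
  times <- marker_times(markers)
  delays <- rep(NA_real_, length(times))
  for (k in seq_along(times)) {
    i1 <- floor((times[k] + search_window[1] - stim_trace$t0) * fs + 0.5) + 1
    i2 <- floor((times[k] + search_window[2] - stim_trace$t0) * fs + 0.5) + 1
    i1 <- max(1L, i1); i2 <- min(n, i2)
    if (i2 <= i1) next
    win <- r[i1:i2]
    mx <- max(win)
    if (mx <= 0) next
    thr <- onset_threshold * mx
    j <- which(win >= thr)[1]
    if (is.na(j)) next
    if (j == 1L) {
      t_cross <- (i1 - 1) / fs
    } else {
      frac <- (thr - win[j - 1]) / (win[j] - win[j - 1])
      t_cross <- (i1 + j - 3 + frac) / fs
    }
    delays[k] <- stim_trace$t0 + t_cross - times[k]
  }
  ok <- !is.na(delays)
  if (!any(ok))
    stop("no detectable onsets in any search window", call. = FALSE)
  d <- delays[ok]
  structure(
    list(mean_delay = mean(d),
         jitter = if (length(d) > 1) stats::sd(d) else 0,
         n_events = length(d),
         n_excluded = sum(!ok),
         delays = d),
    class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> mean delay %.2f ms, jitter %.2f ms (n = %d, excluded %d)\n",
              1e3 * x$mean_delay, 1e3 * x$jitter, x$n_events, x$n_excluded))
  invisible(x)
}
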