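# Vectorized one-sample two-tailed t-test per (channel, sample).
# Zero-variance timepoints take the limit of the t statistic:
# significant (p = 0) when the mean is nonzero, p = 1 otherwise.
one_sample_t_p <- function(m, s, n) {
  p <- matrix(1, nrow(m), ncol(m))
  ok <- s > 0
  t_ok <- m[ok] / (s[ok] / sqrt(n))
  p[ok] <- 2 * stats::pt(-abs(t_ok), df = n - 1)
  p[!ok & m != 0] <- 0
  p
}

#' Trial-averaged evoked response with significance mask
#'
#' Averages epochs across trials and marks timepoints where the trial
#' amplitudes differ from zero by a per-timepoint one-sample two-tailed
#' t-test at level `alpha`, uncorrected for multiple comparisons.
#'
#' @param ep an `eeg_epochs` object with at least 2 trials.
#' @param alpha significance level (default 0.05).
#' @return An object of class `erp_result`: `times`, `mean_wave`
#'   (channels x samples, uV), `sig_mask` (logical, same shape),
#'   `p_values`, `alpha`, `n_trials`, `channel_labels`, and the
#'   `per_trial` array.
#' @export
average_erp <- function(ep, alpha = 0.05) {
  stopifnot(inherits(ep, "eeg_epochs"))
  n <- n_trials(ep)
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  m <- apply(ep$data, c(2, 3), mean)
  s <- apply(ep$data, c(2, 3), stats::sd)
  p <- one_sample_t_p(m, s, n)
  structure(
    list(times = ep$times, mean_wave = m, per_trial = ep$data,
         sig_mask = p < alpha, p_values = p, alpha = alpha, n_trials = n,
         channel_labels = ep$channel_labels),
    class = "erp_result")
}

#' @export
print.erp_result <- function(x, ...) {
  cat(sprintf("<erp_result> %d channel(s) x %d samples, %d trial(s), alpha = %g\n",
              nrow(x$mean_wave), ncol(x$mean_wave), x$n_trials, x$alpha))
  invisible(x)
}

# Standards immediately preceding a deviant, by brute trial-order scan.
standards_before_deviants <- function(labels, standard, deviant) {
  idx <- which(labels == deviant)
  idx <- idx[idx > 1]
  idx <- idx[labels[idx - 1] == standard]
  idx - 1L
}

#' Oddball difference wave (deviant minus preceding standards)
#'
#' Computes the average deviant waveform minus the average of the
#' standard trials that immediately precede a deviant in trial order
#' (other standards are excluded). Timepoints where the two trial
#' groups differ are marked by a per-timepoint two-sample two-tailed
#' Welch t-test at level `alpha`, uncorrected.
#'
#' @param ep an `eeg_epochs` object whose `event_labels` contain both
#'   trial types in marker order.
#' @param standard,deviant labels of the standard and deviant trials.
#' @param alpha significance level (default 0.05).
#' @return An object of class `difference_wave`: `times`, `wave`
#'   (channels x samples, uV), `sig_mask`, `p_values`, `n_pairs`,
#'   `n_deviants`, `standards_used` (trial indices), `alpha`,
#'   `channel_labels`.
#' @export
oddball_difference <- function(ep, standard = "standard",
                               deviant = "deviant", alpha = 0.05) {
  stopifnot(inherits(ep, "eeg_epochs"))
  labels <- ep$event_labels
  dev_idx <- which(labels == deviant)
  if (length(dev_idx) < 2)
    stop("need at least 2 deviant trials", call. = FALSE)
  std_idx <- standards_before_deviants(labels, standard, deviant)
  if (!length(std_idx))
    stop("no standard trials immediately precede a deviant", call. = FALSE)
  d <- ep$data[dev_idx, , , drop = FALSE]
  s <- ep$data[std_idx, , , drop = FALSE]
  n1 <- length(dev_idx); n2 <- length(std_idx)
  m1 <- apply(d, c(2, 3), mean); m2 <- apply(s, c(2, 3), mean)
  v1 <- apply(d, c(2, 3), stats::var); v2 <- apply(s, c(2, 3), stats::var)
  se2 <- v1 / n1 + v2 / n2
  wave <- m1 - m2
  p <- matrix(1, nrow(wave), ncol(wave))
  ok <- se2 > 0
  tt <- wave[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df = df)
  p[!ok & wave != 0] <- 0
  structure(
    list(times = ep$times, wave = wave, sig_mask = p < alpha, p_values = p,
         n_pairs = min(n1, n2), n_deviants = n1,
         standards_used = std_idx, alpha = alpha,
         channel_labels = ep$channel_labels),
    class = "difference_wave")
}

#' @export
print.difference_wave <- function(x, ...) {
  cat(sprintf("<difference_wave> %d channel(s) x %d samples, %d pair(s)\n",
              nrow(x$wave), ncol(x$wave), x$n_pairs))
  invisible(x)
}

#' Default ERP component search windows
#'
#' P1 (0.03-0.08 s, positive), N1 (0.08-0.15 s, negative), P2
#' (0.15-0.3 s, positive), MMN (0.1-0.3 s, negative), P300
#' (0.25-0.5 s, positive). These are search windows, not expected
#' latencies, and are freely configurable.
#'
#' @return A data.frame with columns `name`, `tmin`, `tmax`, `polarity`.
#' @export
default_erp_components <- function() {
  data.frame(
    name = c("P1", "N1", "P2", "MMN", "P300"),
    tmin = c(0.03, 0.08, 0.15, 0.10, 0.25),
    tmax = c(0.08, 0.15, 0.30, 0.30, 0.50),
    polarity = c("positive", "negative", "positive", "negative", "positive"),
    stringsAsFactors = FALSE)
}

wave_of <- function(x) {
  if (inherits(x, "erp_result")) x$mean_wave
  else if (inherits(x, "difference_wave")) x$wave
  else stop("expected an erp_result or difference_wave", call. = FALSE)
}

#' Quantify ERP components
#'
#' For each requested component, finds the signed extremum of the
#' stated polarity inside its search window and its latency (ties break
#' to the earliest sample).
#'
#' @param erp an `erp_result` or `difference_wave`.
#' @param channel channel label.
#' @param components a data.frame like [default_erp_components()]
#'   (columns `name`, `tmin`, `tmax`, `polarity`).
#' @return A data.frame with columns `name`, `peak_amplitude` (uV),
#'   `peak_latency` (s), `tmin`, `tmax`, `polarity`.
#' @export
component_metrics <- function(erp, channel,
                              components = default_erp_components()) {
  w <- wave_of(erp)
  i <- match(channel, erp$channel_labels)
  if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
  x <- w[i, ]
  tms <- erp$times
  rows <- lapply(seq_len(nrow(components)), function(k) {
    cm <- components[k, ]
    idx <- which(tms >= cm$tmin & tms <= cm$tmax)
    if (!length(idx))
      stop("component window [", cm$tmin, ", ", cm$tmax,
           "] outside the epoch span", call. = FALSE)
    j <- if (cm$polarity == "negative") idx[which.min(x[idx])]
         else idx[which.max(x[idx])]
    data.frame(name = cm$name, peak_amplitude = x[j], peak_latency = tms[j],
               tmin = cm$tmin, tmax = cm$tmax, polarity = cm$polarity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peak-to-peak amplitude between two components
#'
#' @param metrics output of [component_metrics()].
#' @param a,b component names (e.g. `"N1"`, `"P2"`).
#' @return Absolute amplitude difference in uV.
#' @export
peak_to_peak <- function(metrics, a, b) {
  ia <- match(a, metrics$name); ib <- match(b, metrics$name)
  if (is.na(ia) || is.na(ib))
    stop("component not found in metrics", call. = FALSE)
  abs(metrics$peak_amplitude[ia] - metrics$peak_amplitude[ib])
}

#' Grand average across subject-level ERPs
#'
#' Unweighted mean of subject-level mean waveforms (one recording file
#' per subject).
#'
#' @param erps list of `erp_result` objects with identical shapes.
#' @return An `erp_result` whose `mean_wave` is the unweighted mean;
#'   the significance mask is a one-sample t-test across subjects.
#' @export
grand_average <- function(erps) {
  stopifnot(length(erps) >= 1)
  waves <- lapply(erps, wave_of)
  d <- dim(waves[[1]])
  arr <- array(unlist(waves), dim = c(d[1], d[2], length(waves)))
  m <- apply(arr, c(1, 2), mean)
  if (length(erps) >= 2) {
    s <- apply(arr, c(1, 2), stats::sd)
    p <- one_sample_t_p(m, s, length(erps))
  } else p <- matrix(1, d[1], d[2])
  structure(
    list(times = erps[[1]]$times, mean_wave = m, per_trial = arr,
         sig_mask = p < erps[[1]]$alpha, p_values = p,
         alpha = erps[[1]]$alpha, n_trials = length(erps),
         channel_labels = erps[[1]]$channel_labels),
    class = "erp_result")
}
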