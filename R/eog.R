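#' Blink amplitude metrics
#'
#' Quantifies intentional ("hard") versus regular ("soft") blinks as
#' the mean over trials of the within-window peak-to-peak amplitude,
#' and their ratio. Epochs are expected to be filtered to the blink
#' band (0.2-3 Hz) beforehand.
#'
#' @param ep_hard,ep_soft `eeg_epochs` for the two blink conditions.
#' @param channel channel label (present in both).
#' @return An object of class `blink_metrics`: `p2p_hard`, `p2p_soft`
#'   (uV), `ratio` (hard/soft), `n_hard`, `n_soft`, `channel`.
#' @export
blink_metrics <- function(ep_hard, ep_soft, channel) {
  stopifnot(inherits(ep_hard, "eeg_epochs"), inherits(ep_soft, "eeg_epochs"))
  p2p <- function(ep) {
    i <- match(channel, ep$channel_labels)
    if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
    x <- ep$data[, i, , drop = FALSE]
    mean(apply(x, 1, function(tr) max(tr) - min(tr)))
  }
  if (n_trials(ep_hard) < 1 || n_trials(ep_soft) < 1)
    stop("each blink condition needs at least one trial", call. = FALSE)
  h <- p2p(ep_hard); s <- p2p(ep_soft)
  structure(
    list(p2p_hard = h, p2p_soft = s, ratio = h / s,
         n_hard = n_trials(ep_hard), n_soft = n_trials(ep_soft),
         channel = channel),
    class = "blink_metrics")
}

#' @export
print.blink_metrics <- function(x, ...) {
  cat(sprintf("<blink_metrics> %s: hard %.0f uV / soft %.0f uV, ratio %.2f\n",
              x$channel, x$p2p_hard, x$p2p_soft, x$ratio))
  invisible(x)
}

#' Per-direction saccade profiles
#'
#' Averages saccade epochs per movement direction and evaluates the
#' amplitude at the assessment time (default 200 ms post-stimulus,
#' where direction separation is greatest), at the nearest sample.
#'
#' @param ep an `eeg_epochs` object labeled by direction.
#' @param channel channel label.
#' @param assessment_time evaluation time in seconds (default 0.2).
#' @param labels named character vector mapping directions to trial
#'   labels; default `c(up = "saccade_up", ..., right = "saccade_right")`.
#' @return A named list of `saccade_profile` objects (one per
#'   direction): `direction`, `times`, `wave` (uV), `amplitude_at_t`,
#'   `assessment_time`, `n_trials`.
#' @export
saccade_profiles <- function(ep, channel, assessment_time = 0.2,
                             labels = c(up = "saccade_up",
                                        down = "saccade_down",
                                        left = "saccade_left",
                                        right = "saccade_right")) {
  stopifnot(inherits(ep, "eeg_epochs"))
  if (assessment_time < ep$window[1] || assessment_time > ep$window[2])
    stop("assessment_time outside the epoch window", call. = FALSE)
  i <- match(channel, ep$channel_labels)
  if (is.na(i)) stop("channel not found: ", channel, call. = FALSE)
  missing_dir <- names(labels)[!(labels %in% ep$event_labels)]
  if (length(missing_dir))
    stop("missing direction(s): ", paste(missing_dir, collapse = ", "),
         call. = FALSE)
  j <- which.min(abs(ep$times - assessment_time))
  out <- lapply(names(labels), function(d) {
    tr <- which(ep$event_labels == labels[[d]])
    w <- apply(ep$data[tr, i, , drop = FALSE], 3, mean)
    structure(
      list(direction = d, times = ep$times, wave = w,
           amplitude_at_t = w[j], assessment_time = ep$times[j],
           n_trials = length(tr)),
      class = "saccade_profile")
  })
  stats::setNames(out, names(labels))
}

#' @export
print.saccade_profile <- function(x, ...) {
  cat(sprintf("<saccade_profile> %s: %.2f uV at %g s (%d trials)\n",
              x$direction, x$amplitude_at_t, x$assessment_time, x$n_trials))
  invisible(x)
}

#' Separation between opposing saccade directions
#'
#' Absolute amplitude difference at the assessment time between the two
#' directions of an axis (`left`/`right` or `up`/`down`). Symmetric in
#' its two directions and non-negative.
#'
#' @param profiles output of [saccade_profiles()].
#' @param axis `"horizontal"` or `"vertical"`.
#' @return Separation in uV.
#' @export
direction_separation <- function(profiles, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  pair <- if (axis == "horizontal") c("left", "right") else c("up", "down")
  if (!all(pair %in% names(profiles)))
    stop("profiles lack direction(s): ",
         paste(setdiff(pair, names(profiles)), collapse = ", "), call. = FALSE)
  abs(profiles[[pair[1]]]$amplitude_at_t - profiles[[pair[2]]]$amplitude_at_t)
}
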