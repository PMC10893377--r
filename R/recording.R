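#' Multichannel EEG recording
#'
#' Container for a uniformly sampled multichannel recording. Amplitudes are
#' stored in microvolts as a channels-by-samples matrix together with the
#' sampling rate, ordered channel labels, the start time of the first
#' sample and the label of the current reference electrode.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of unique labels, one per row of
#'   `data`.
#' @param t0 timestamp of the first sample in seconds.
#' @param reference_label label of the electrode the data are referenced
#'   to (e.g. `"FCz"`, `"Cz"`, `"ER3"`), or `NA` if unknown.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(1000), 2), fs = 500,
#'                  channel_labels = c("Cz", "Oz"))
#' n_samples(rec)
#' @export
recording <- function(data, fs, channel_labels, t0 = 0,
                      reference_label = NA_character_) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("`channel_labels` must have one entry per data row", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         t0 = t0, reference_label = reference_label),
    class = "eeg_recording")
}

#' @rdname recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Sample times of a recording
#'
#' @param rec an `eeg_recording`.
#' @return numeric vector `t0 + (0:(n-1))/fs`.
#' @export
sample_times <- function(rec) rec$t0 + (seq_len(n_samples(rec)) - 1) / rec$fs

# Resolve a channel label to its row index, with an informative error.
channel_index <- function(rec, label) {
  i <- match(label, rec$channel_labels)
  if (anyNA(i))
    stop("channel(s) not found: ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  i
}

#' Subset a recording to selected channels
#'
#' @param rec an `eeg_recording`.
#' @param labels channel labels to keep, in the requested order.
#' @return An `eeg_recording` with only those channels.
#' @export
select_channels <- function(rec, labels) {
  i <- channel_index(rec, labels)
  recording(rec$data[i, , drop = FALSE], rec$fs, rec$channel_labels[i],
            t0 = rec$t0, reference_label = rec$reference_label)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat("  channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  cat("  reference:", x$reference_label, " t0:", x$t0, "\n")
  invisible(x)
}

#' Timestamped marker stream
#'
#' Ordered event markers that delimit paradigms and stimuli. Timestamps
#' are in seconds; `clock_offset` is the offset of the marker clock
#' relative to the recording clock (an event at marker-clock time `t`
#' occurred at recording-clock time `t + clock_offset`).
#'
#' @param time numeric vector of non-decreasing timestamps (s).
#' @param label character vector of non-empty event labels.
#' @param clock_offset offset of the marker clock relative to the
#'   recording clock, in seconds (default 0).
#' @return An object of class `marker_stream` with fields `events`
#'   (data.frame with columns `time`, `label`) and `clock_offset`.
#' @export
marker_stream <- function(time = numeric(), label = character(),
                          clock_offset = 0) {
  time <- as.numeric(time)
  label <- as.character(label)
  stopifnot(length(time) == length(label))
  if (length(time) > 1 && any(diff(time) < 0))
    stop("marker timestamps must be non-decreasing", call. = FALSE)
  if (any(!nzchar(label)))
    stop("marker labels must be non-empty", call. = FALSE)
  structure(
    list(events = data.frame(time = time, label = label,
                             stringsAsFactors = FALSE),
         clock_offset = clock_offset),
    class = "marker_stream")
}

#' Marker times expressed on the recording clock
#'
#' @param markers a `marker_stream`.
#' @return numeric vector of event times plus the stream's clock offset.
#' @export
marker_times <- function(markers) markers$events$time + markers$clock_offset

#' @export
print.marker_stream <- function(x, ...) {
  cat(sprintf("<marker_stream> %d event(s), clock_offset = %g s\n",
              nrow(x$events), x$clock_offset))
  if (nrow(x$events)) print(utils::head(x$events, 6))
  invisible(x)
}

#' Electrode montage
#'
#' Groups channel labels into the 12-channel scalp set and the two 8-sensor
#' ear sets, with an optional role map (recording / reference / ground).
#'
#' @param scalp_labels ordered scalp channel labels.
#' @param ear_labels ordered ear channel labels.
#' @param role_map named character vector mapping labels to roles
#'   (`"recording"`, `"reference"`, `"ground"`).
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(scalp_labels, ear_labels, role_map = character()) {
  scalp_labels <- as.character(scalp_labels)
  ear_labels <- as.character(ear_labels)
  if (length(intersect(scalp_labels, ear_labels)))
    stop("a label cannot be both a scalp and an ear channel", call. = FALSE)
  all_labels <- c(scalp_labels, ear_labels)
  if (length(role_map) && !all(names(role_map) %in% c(all_labels, "FCz", "AFz")))
    stop("role_map keys must be montage labels", call. = FALSE)
  structure(list(scalp_labels = scalp_labels, ear_labels = ear_labels,
                 role_map = role_map),
            class = "eeg_montage")
}

#' Default scalp + two-ear montage
#'
#' The 12 scalp positions used for benchmarking (F3, Fz, F4, T7, C3, Cz,
#' C4, T8, P3, Pz, P4, Oz) plus eight sensors per ear (EL1-EL8, ER1-ER8).
#'
#' @return An `eeg_montage`.
#' @export
default_montage <- function() {
  montage(
    scalp_labels = c("F3", "Fz", "F4", "T7", "C3", "Cz", "C4", "T8",
                     "P3", "Pz", "P4", "Oz"),
    ear_labels = c(paste0("EL", 1:8), paste0("ER", 1:8)),
    role_map = c(FCz = "reference", AFz = "ground"))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage>\n  scalp:", paste(x$scalp_labels, collapse = " "),
      "\n  ear:  ", paste(x$ear_labels, collapse = " "), "\n")
  invisible(x)
}

montage_labels <- function(m) c(m$scalp_labels, m$ear_labels)
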