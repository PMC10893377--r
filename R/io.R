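#' Write a recording and its markers to disk
#'
#' Serializes an [recording()] plus [marker_stream()] as a plain-text
#' session directory: `meta.json` (sampling rate, labels, start time,
#' reference, marker clock offset), `data.csv` (a `time` column followed
#' by one column per channel, in microvolts) and `events.csv`
#' (columns `time`, `label`, on the marker clock). The format is the
#' package's text dialect of an XDF-style one-EEG-stream / one-marker-
#' stream session and round-trips through [read_recording()] with exact
#' labels and sampling rate and float-tolerant data.
#'
#' @param rec an `eeg_recording`.
#' @param markers a `marker_stream` (may be empty).
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, markers = marker_stream(), path) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(markers, "marker_stream"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path, call. = FALSE)
  meta <- list(format = "earval-session", version = 1L,
               fs = rec$fs, channel_labels = rec$channel_labels,
               t0 = rec$t0, reference_label = rec$reference_label,
               clock_offset = markers$clock_offset)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  dat <- data.table::data.table(time = sample_times(rec))
  for (i in seq_len(n_channels(rec)))
    data.table::set(dat, j = rec$channel_labels[i], value = rec$data[i, ])
  data.table::fwrite(dat, file.path(path, "data.csv"))
  data.table::fwrite(markers$events, file.path(path, "events.csv"))
  invisible(path)
}

#' Read a recording and its markers from disk
#'
#' Reads a session directory written by [write_recording()] (or assembled
#' by hand in the same layout). The EEG stream is regularized onto a
#' uniform grid at the nominal sampling rate: if the stored timestamps
#' deviate from a uniform grid, the first and last timestamps are mapped
#' linearly onto a grid at `fs` and each channel is linearly
#' interpolated onto it. Marker timestamps are returned expressed on the
#' recording clock (the stored clock offset is applied and reset to 0).
#'
#' @param path session directory.
#' @return A list with elements `recording` (an `eeg_recording`) and
#'   `markers` (a `marker_stream` on the recording clock).
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stop("no such session directory: ", path, call. = FALSE)
  meta_file <- file.path(path, "meta.json")
  data_file <- file.path(path, "data.csv")
  if (!file.exists(meta_file) || !file.exists(data_file))
    stop("not a session directory (missing meta.json or data.csv): ",
         path, call. = FALSE)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$format, "earval-session"))
    stop("unrecognized session format in ", meta_file, call. = FALSE)
  dat <- data.table::fread(data_file)
  labels <- as.character(meta$channel_labels)
  missing_ch <- setdiff(labels, names(dat))
  if (length(missing_ch))
    stop("data.csv lacks channel column(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  fs <- as.numeric(meta$fs)
  x <- t(as.matrix(dat[, labels, with = FALSE]))
  if ("time" %in% names(dat) && ncol(x) > 1) {
    ts <- dat$time
    grid0 <- ts[1] + (seq_along(ts) - 1) / fs
    if (max(abs(ts - grid0)) > 1e-9 / fs + 1e-9) {
      # irregular timestamps: linear first/last mapping onto nominal grid
      n_out <- max(2L, round((ts[length(ts)] - ts[1]) * fs) + 1L)
      grid <- ts[1] + (seq_len(n_out) - 1) / fs
      x <- t(apply(x, 1, function(ch)
        stats::approx(ts, ch, xout = grid, rule = 2)$y))
      t0 <- ts[1]
    } else t0 <- ts[1]
  } else {
    t0 <- if (is.null(meta$t0)) 0 else as.numeric(meta$t0)
  }
  rec <- recording(x, fs = fs, channel_labels = labels, t0 = t0,
                   reference_label = if (is.null(meta$reference_label))
                     NA_character_ else meta$reference_label)
  ev_file <- file.path(path, "events.csv")
  offset <- if (is.null(meta$clock_offset)) 0 else meta$clock_offset
  if (file.exists(ev_file) && file.size(ev_file) > 2) {
    ev <- data.table::fread(ev_file)
    if (nrow(ev)) {
      mk <- marker_stream(ev$time + offset, ev$label, clock_offset = 0)
    } else mk <- marker_stream()
  } else mk <- marker_stream()
  list(recording = rec, markers = mk)
}
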