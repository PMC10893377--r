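canonical_paradigm <- function(paradigm) {
  switch(paradigm,
         mmn = "aep_oddball", p300 = "vep_oddball",
         alpha = "alpha_block", paradigm)
}

analysis_defaults <- function(paradigm) {
  freq_filter <- list(highpass_hz = 1, lowpass_hz = 100, notch_hz = 50)
  erp_filter <- list(highpass_hz = 1, lowpass_hz = 20, notch_hz = NULL)
  switch(paradigm,
    resting = list(filter = freq_filter, window_s = 8),
    alpha_block = list(filter = freq_filter, window_s = 2,
                       closed_label = "eyes_closed",
                       open_label = "eyes_open", settle_s = 2,
                       alpha_band = c(8, 12)),
    assr = list(filter = freq_filter, f0 = 40, band = c(35, 45),
                window_s = 8),
    ssvep = list(filter = freq_filter, f0 = 10, band = c(5, 15),
                 window_s = 8),
    aep = list(filter = erp_filter, epoch_window = c(-0.1, 0.5),
               baseline = c(-0.1, 0), latency_correction = 0,
               stim_label = "stim", components = c("P1", "N1", "P2")),
    vep = list(filter = erp_filter, epoch_window = c(-0.1, 0.5),
               baseline = c(-0.1, 0), latency_correction = 0.021,
               stim_label = "stim", components = c("P1", "N1", "P2")),
    aep_oddball = list(filter = erp_filter, epoch_window = c(-0.1, 0.5),
                       baseline = c(-0.1, 0), latency_correction = 0,
                       components = "MMN"),
    vep_oddball = list(filter = erp_filter, epoch_window = c(-0.1, 0.8),
                       baseline = c(-0.1, 0), latency_correction = 0.021,
                       components = "P300"),
    eog = list(saccade_filter = erp_filter,
               blink_filter = list(highpass_hz = 0.2, lowpass_hz = 3,
                                   notch_hz = NULL),
               saccade_window = c(-0.1, 0.5), blink_window = c(-1, 2),
               baseline = c(-0.1, 0), latency_correction = 0.021,
               assessment_time = 0.2),
    stop("unknown paradigm: ", paradigm, call. = FALSE))
}

#' Analysis configuration for one paradigm
#'
#' Bundles the processing-chain parameters used by [run_analysis()]:
#' filter band (1-100 Hz for frequency paradigms, 1-20 Hz for
#' transients, 0.2-3 Hz for blinks, all with a 50 Hz notch where set),
#' reference scheme (default Cz), epoch window and 100 ms pre-stimulus
#' baseline, per-chain trigger-latency correction (0 ms auditory,
#' 21 ms visual) and significance level. Any default can be
#' overridden by name.
#'
#' @param paradigm paradigm name (aliases `"mmn"`, `"p300"` and
#'   `"alpha"` are accepted).
#' @param reference reference channel label, or `"none"` to analyse
#'   the data as recorded.
#' @param channels channels of interest (`NULL` = all channels except
#'   the reference).
#' @param alpha_level significance level for the paradigm's test
#'   (default 0.05).
#' @param ... overrides of the per-paradigm defaults (see
#'   `earval:::analysis_defaults`).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(paradigm, reference = "Cz", channels = NULL,
                            alpha_level = 0.05, ...) {
  paradigm <- canonical_paradigm(paradigm)
  cfg <- analysis_defaults(paradigm)
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "latency_correction"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  cfg$paradigm <- paradigm
  cfg$reference <- reference
  cfg$channels <- channels
  cfg$alpha_level <- alpha_level
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> %s (reference %s, alpha %g)\n",
              x$paradigm, x$reference, x$alpha_level))
  invisible(x)
}

as_filter_spec <- function(f) {
  filter_spec(f$highpass_hz, f$lowpass_hz, notch_hz = f$notch_hz)
}

prepare_recording <- function(rec, filter_def, reference) {
  rec <- apply_filter_chain(rec, as_filter_spec(filter_def))
  if (!identical(reference, "none")) rec <- rereference(rec, reference)
  rec
}

channels_of_interest <- function(rec, config) {
  ch <- config$channels %||% setdiff(rec$channel_labels, config$reference)
  ch
}

metric_row <- function(paradigm, channel, reference, metric, value,
                       p = NA_real_, significant = NA) {
  data.frame(paradigm = paradigm, channel = channel, reference = reference,
             metric = metric, value = value, p = p,
             significant = significant, stringsAsFactors = FALSE)
}

run_snr_paradigm <- function(rec, config) {
  psd <- welch_psd(rec, window_s = config$window_s)
  rows <- lapply(channels_of_interest(rec, config), function(ch) {
    r <- narrowband_snr(psd, ch, config$f0, config$band,
                        alpha = config$alpha_level)
    metric_row(config$paradigm, ch, config$reference, "snr_db",
               r$snr_db, r$p_value, r$significant)
  })
  do.call(rbind, rows)
}

run_alpha_block <- function(rec, markers, config) {
  spg <- stft_spectrogram(rec, window_s = config$window_s)
  iv <- condition_intervals(markers,
                            c(config$closed_label, config$open_label),
                            end_time = rec$t0 + n_samples(rec) / rec$fs,
                            settle_s = config$settle_s)
  rows <- lapply(channels_of_interest(rec, config), function(ch) {
    r <- alpha_modulation(spg, ch, iv[[config$closed_label]],
                          iv[[config$open_label]],
                          alpha_band = config$alpha_band)
    metric_row(config$paradigm, ch, config$reference, "ram_db", r$ram_db)
  })
  do.call(rbind, rows)
}

run_erp_paradigm <- function(rec, markers, config) {
  ep <- extract_epochs(rec, markers, config$stim_label,
                       config$epoch_window,
                       latency_correction = config$latency_correction)
  ep <- baseline_correct(ep, config$baseline)
  erp <- average_erp(ep, alpha = config$alpha_level)
  comps <- default_erp_components()
  comps <- comps[comps$name %in% config$components, , drop = FALSE]
  rows <- lapply(channels_of_interest(rec, config), function(ch) {
    cm <- component_metrics(erp, ch, comps)
    do.call(rbind, lapply(seq_len(nrow(cm)), function(k) rbind(
      metric_row(config$paradigm, ch, config$reference,
                 paste0(cm$name[k], "_amplitude"), cm$peak_amplitude[k]),
      metric_row(config$paradigm, ch, config$reference,
                 paste0(cm$name[k], "_latency"), cm$peak_latency[k]))))
  })
  do.call(rbind, rows)
}

run_oddball_paradigm <- function(rec, markers, config) {
  ep <- extract_epochs(rec, markers, c("standard", "deviant"),
                       config$epoch_window,
                       latency_correction = config$latency_correction)
  ep <- baseline_correct(ep, config$baseline)
  dw <- oddball_difference(ep, alpha = config$alpha_level)
  comps <- default_erp_components()
  comps <- comps[comps$name %in% config$components, , drop = FALSE]
  rows <- lapply(channels_of_interest(rec, config), function(ch) {
    cm <- component_metrics(dw, ch, comps)
    do.call(rbind, lapply(seq_len(nrow(cm)), function(k) rbind(
      metric_row(config$paradigm, ch, config$reference,
                 paste0(cm$name[k], "_amplitude"), cm$peak_amplitude[k]),
      metric_row(config$paradigm, ch, config$reference,
                 paste0(cm$name[k], "_latency"), cm$peak_latency[k]))))
  })
  do.call(rbind, rows)
}

run_eog_paradigm <- function(rec_raw, markers, config) {
  # blinks: 0.2-3 Hz chain
  rec_b <- prepare_recording(rec_raw, config$blink_filter, config$reference)
  ep_h <- extract_epochs(rec_b, markers, "blink_hard", config$blink_window,
                         latency_correction = config$latency_correction)
  ep_s <- extract_epochs(rec_b, markers, "blink_soft", config$blink_window,
                         latency_correction = config$latency_correction)
  # saccades: 1-20 Hz chain
  rec_s <- prepare_recording(rec_raw, config$saccade_filter, config$reference)
  ep_sac <- extract_epochs(rec_s, markers,
                           paste0("saccade_", c("up", "down", "left", "right")),
                           config$saccade_window,
                           latency_correction = config$latency_correction)
  ep_sac <- baseline_correct(ep_sac, config$baseline)
  rows <- lapply(channels_of_interest(rec_raw, config), function(ch) {
    bm <- blink_metrics(ep_h, ep_s, ch)
    pr <- saccade_profiles(ep_sac, ch,
                           assessment_time = config$assessment_time)
    rbind(
      metric_row("eog", ch, config$reference, "blink_ratio", bm$ratio),
      metric_row("eog", ch, config$reference, "blink_p2p_hard", bm$p2p_hard),
      metric_row("eog", ch, config$reference, "blink_p2p_soft", bm$p2p_soft),
      metric_row("eog", ch, config$reference, "saccade_sep_horizontal",
                 direction_separation(pr, "horizontal")),
      metric_row("eog", ch, config$reference, "saccade_sep_vertical",
                 direction_separation(pr, "vertical")))
  })
  do.call(rbind, rows)
}

run_resting <- function(rec, config) {
  psd <- welch_psd(rec, window_s = config$window_s)
  bands <- list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
                beta = c(12, 30), gamma = c(30, 45))
  rows <- lapply(channels_of_interest(rec, config), function(ch) {
    i <- match(ch, psd$channel_labels)
    do.call(rbind, lapply(names(bands), function(b) {
      ib <- band_bins(psd$freqs, bands[[b]])
      metric_row("resting", ch, config$reference,
                 paste0(b, "_power"), mean(psd$power[i, ib]))
    }))
  })
  do.call(rbind, rows)
}

#' Run the full analysis chain for one paradigm
#'
#' Reads (or takes) a recording plus markers, applies the paradigm's
#' filter chain and reference scheme, and computes its metrics:
#' narrowband SNR per channel (ASSR/SSVEP), alpha modulation
#' (alpha block), ERP component amplitudes and latencies (AEP/VEP),
#' difference-wave components (oddballs), blink ratios and saccade
#' separations (EOG), or band-power summaries (resting). Deterministic
#' given the same inputs and configuration.
#'
#' @param x path to a session directory (see [read_recording()]) or an
#'   `eeg_recording`.
#' @param config an [analysis_config()].
#' @param markers a `marker_stream` (required when `x` is a recording;
#'   ignored when `x` is a path).
#' @param out_dir optional directory: writes `metrics.csv` and a
#'   machine-readable `config.json` echo of every parameter used.
#' @return A data.frame with columns `paradigm`, `channel`,
#'   `reference`, `metric`, `value`, `p`, `significant`.
#' @export
run_analysis <- function(x, config, markers = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.character(x)) {
    ses <- read_recording(x)
    rec <- ses$recording; markers <- ses$markers
  } else {
    rec <- x
    markers <- markers %||% marker_stream()
  }
  stopifnot(inherits(rec, "eeg_recording"))
  p <- config$paradigm
  res <- if (p == "eog") {
    run_eog_paradigm(rec, markers, config)
  } else {
    prepped <- prepare_recording(rec, config$filter %||% config$saccade_filter,
                                 config$reference)
    switch(p,
      assr = run_snr_paradigm(prepped, config),
      ssvep = run_snr_paradigm(prepped, config),
      alpha_block = run_alpha_block(prepped, markers, config),
      aep = run_erp_paradigm(prepped, markers, config),
      vep = run_erp_paradigm(prepped, markers, config),
      aep_oddball = run_oddball_paradigm(prepped, markers, config),
      vep_oddball = run_oddball_paradigm(prepped, markers, config),
      resting = run_resting(prepped, config),
      stop("no analysis for paradigm: ", p, call. = FALSE))
  }
  rownames(res) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  res
}

#' Load an analysis configuration from YAML
#'
#' Reads a per-paradigm parameter file in the layout of the shipped
#' `inst/extdata/default_config.yaml` and builds the corresponding
#' [analysis_config()]. Top-level `reference` and `alpha_level` apply
#' to every paradigm; entries under `paradigms:` override the built-in
#' defaults field by field.
#'
#' @param paradigm paradigm name.
#' @param path YAML file; defaults to the configuration shipped with
#'   the package.
#' @param channels optional channels of interest.
#' @return An `analysis_config`.
#' @export
load_analysis_config <- function(paradigm,
                                 path = system.file("extdata",
                                                    "default_config.yaml",
                                                    package = "earval"),
                                 channels = NULL) {
  y <- yaml::read_yaml(path)
  paradigm <- canonical_paradigm(paradigm)
  overrides <- y$paradigms[[paradigm]] %||% list()
  # YAML lists arrive as plain vectors/lists; normalize interval fields
  for (nm in intersect(names(overrides),
                       c("epoch_window", "baseline", "band", "alpha_band",
                         "saccade_window", "blink_window")))
    overrides[[nm]] <- as.numeric(unlist(overrides[[nm]]))
  for (nm in intersect(names(overrides), c("components")))
    overrides[[nm]] <- as.character(unlist(overrides[[nm]]))
  do.call(analysis_config,
          c(list(paradigm = paradigm,
                 reference = y$reference %||% "Cz",
                 channels = channels,
                 alpha_level = y$alpha_level %||% 0.05),
            overrides))
}

primary_metric_for <- function(paradigm) {
  switch(paradigm,
         assr = "snr_db", ssvep = "snr_db", alpha_block = "ram_db",
         stop("compare_references supports the spectral paradigms ",
              "(assr, ssvep, alpha_block)", call. = FALSE))
}

#' Compare reference configurations
#'
#' Re-runs a spectral paradigm's analysis under several reference
#' schemes (e.g. Cz, T8, a within-ear ER3 or a between-ear reference)
#' and ranks them by the paradigm's primary metric at the channels of
#' interest, with deltas in dB relative to the first listed reference.
#'
#' @param x path or `eeg_recording` (see [run_analysis()]).
#' @param config an [analysis_config()] for `assr`, `ssvep` or
#'   `alpha_block`; `config$channels` should name the channel(s) of
#'   interest (they must not be among `references`).
#' @param references character vector of reference labels (or
#'   `"none"`); deltas are relative to the first.
#' @param markers marker stream when `x` is a recording.
#' @return A data.frame with columns `reference`, `value` (mean
#'   primary metric in dB over the channels of interest), `delta_db`,
#'   sorted by decreasing value.
#' @export
compare_references <- function(x, config, references, markers = NULL) {
  stopifnot(length(references) >= 1)
  metric <- primary_metric_for(config$paradigm)
  if (is.character(x)) {
    ses <- read_recording(x)
    x <- ses$recording; markers <- ses$markers
  }
  bad <- intersect(config$channels %||% character(), references)
  if (length(bad))
    stop("channel(s) of interest cannot also be references: ",
         paste(bad, collapse = ", "), call. = FALSE)
  vals <- vapply(references, function(ref) {
    cfg <- config
    cfg$reference <- ref
    res <- run_analysis(x, cfg, markers = markers)
    mean(res$value[res$metric == metric])
  }, numeric(1))
  out <- data.frame(reference = references, value = unname(vals),
                    delta_db = unname(vals - vals[1]),
                    stringsAsFactors = FALSE)
  out[order(-out$value), , drop = FALSE]
}
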