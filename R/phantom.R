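apply_rounding <- function(x, rounding) {
  switch(rounding,
         up = ceiling(x),
         nearest = round(x),
         none = x,
         stop("unknown rounding rule: ", rounding, call. = FALSE))
}

new_mixture_recipe <- function(material, base_name, base_value,
                               masses, exact, fractions, rounding) {
  structure(
    list(material = material, base_name = base_name, base_value = base_value,
         component_masses = masses, exact_masses = exact,
         weight_fractions = fractions, rounding = rounding),
    class = "mixture_recipe")
}

#' @export
print.mixture_recipe <- function(x, ...) {
  cat(sprintf("<mixture_recipe> %s (%s = %g)\n", x$material,
              x$base_name, x$base_value))
  for (nm in names(x$component_masses))
    cat(sprintf("  %s: %g g (target %.3g%% w/w)\n", nm,
                x$component_masses[[nm]], 100 * x$weight_fractions[[nm]]))
  invisible(x)
}

# Solve component masses for target weight percentages of the final
# mixture given a base mass: with total T = base / (1 - sum(pct)/100),
# each component mass is pct/100 * T.
solve_weight_fractions <- function(base_g, pcts) {
  if (any(pcts <= 0) || any(pcts >= 100) || sum(pcts) >= 100)
    stop("weight percentages must be in (0, 100) and sum below 100",
         call. = FALSE)
  total <- base_g / (1 - sum(pcts) / 100)
  pcts / 100 * total
}

#' Salt-doped agar mixture recipe
#'
#' Component masses for an agar phantom at the recommended weight
#' percentages (4% agar, 0.5% salt of the final mixture). At the
#' defaults the closed form reduces to agar = 8w/191 and salt = w/191
#' for water mass w; the reference 700 g water fill yields 30 g agar
#' and 4 g salt after rounding up to the nearest gram.
#'
#' @param water_g mass of water in grams (>= 0).
#' @param agar_pct,salt_pct target weight percentages of the final
#'   mixture (defaults 4 and 0.5).
#' @param rounding `"up"` (default), `"nearest"` or `"none"`.
#' @return A `mixture_recipe` with components `agar` and `salt`;
#'   `exact_masses` holds the unrounded values.
#' @export
mixture_agar <- function(water_g, agar_pct = 4.0, salt_pct = 0.5,
                         rounding = "up") {
  if (water_g < 0) stop("`water_g` must be non-negative", call. = FALSE)
  if (water_g == 0) {
    exact <- c(agar = 0, salt = 0)
  } else {
    m <- solve_weight_fractions(water_g, c(agar_pct, salt_pct))
    exact <- c(agar = m[1], salt = m[2])
  }
  new_mixture_recipe("agar", "water_g", water_g,
                     as.list(apply_rounding(exact, rounding)),
                     as.list(exact),
                     list(agar = agar_pct / 100, salt = salt_pct / 100),
                     rounding)
}

#' Salt-doped ballistic gelatin mixture recipe
#'
#' Component masses for a ballistic-gelatin phantom at 15% gelatin and
#' 8% NaCl of the final mixture: gelatin = 15w/77 and salt = 8w/77 for
#' water mass w. No rounding is applied by default.
#'
#' @param water_g mass of water in grams (>= 0).
#' @param gel_pct,salt_pct target weight percentages (defaults 15, 8).
#' @param rounding `"up"`, `"nearest"` or `"none"` (default).
#' @return A `mixture_recipe` with components `gelatin` and `salt`.
#' @export
mixture_bg <- function(water_g, gel_pct = 15.0, salt_pct = 8.0,
                       rounding = "none") {
  if (water_g < 0) stop("`water_g` must be non-negative", call. = FALSE)
  if (water_g == 0) {
    exact <- c(gelatin = 0, salt = 0)
  } else {
    m <- solve_weight_fractions(water_g, c(gel_pct, salt_pct))
    exact <- c(gelatin = m[1], salt = m[2])
  }
  new_mixture_recipe("bg", "water_g", water_g,
                     as.list(apply_rounding(exact, rounding)),
                     as.list(exact),
                     list(gelatin = gel_pct / 100, salt = salt_pct / 100),
                     rounding)
}

#' Carbon-fiber-doped silicone mixture recipe
#'
#' Carbon-fiber mass for a silicone phantom: with silicone mass
#' S = volume x density, the fiber mass at a target weight percentage X
#' of the fiber+silicone mixture is CF = S * X / (100 - X) (CF = S/199
#' at 0.5%, S/99 at 1.0%). Percentages above 1.0% are allowed but emit
#' a feasibility warning: the mixture becomes too dense to mold.
#'
#' @param silicone_ml silicone volume in mL (>= 0).
#' @param density_g_per_ml silicone density (default 1.11 g/mL).
#' @param cf_pct carbon-fiber weight percentage (default 1.0).
#' @param rounding `"up"`, `"nearest"` (default) or `"none"`.
#' @return A `mixture_recipe` with component `carbon_fiber` and the
#'   silicone mass in `component_masses$silicone`.
#' @export
mixture_cf <- function(silicone_ml, density_g_per_ml = 1.11, cf_pct = 1.0,
                       rounding = "nearest") {
  if (silicone_ml < 0 || density_g_per_ml <= 0 || cf_pct < 0)
    stop("inputs must be non-negative (density positive)", call. = FALSE)
  if (cf_pct >= 100) stop("`cf_pct` must be below 100", call. = FALSE)
  if (cf_pct > 1.0)
    warning("carbon-fiber loadings above 1.0% w/w make the mixture too ",
            "dense to mold reliably", call. = FALSE)
  S <- silicone_ml * density_g_per_ml
  cf <- S * cf_pct / (100 - cf_pct)
  new_mixture_recipe("cf_silicone", "silicone_ml", silicone_ml,
                     list(carbon_fiber = apply_rounding(cf, rounding),
                          silicone = S),
                     list(carbon_fiber = cf, silicone = S),
                     list(carbon_fiber = cf_pct / 100),
                     rounding)
}

#' Conductivity from a two-wire resistance measurement
#'
#' Converts a resistance measured across a material strip into
#' resistivity and conductivity: sigma = L / (R * A). Defaults encode
#' the 30 x 10 x 2 mm test-strip geometry (L = 0.03 m, A = 2e-5 m^2).
#'
#' @param resistance_ohm measured resistance (Ohm, > 0).
#' @param length_m conduction path length (m, > 0).
#' @param cross_section_m2 cross-sectional area (m^2, > 0).
#' @return An object of class `conductivity_measure`: `resistance`,
#'   `length`, `cross_section`, `resistivity` (Ohm m), `conductivity`
#'   (S/m).
#' @export
conductivity <- function(resistance_ohm, length_m = 0.03,
                         cross_section_m2 = 2e-5) {
  if (resistance_ohm <= 0 || length_m <= 0 || cross_section_m2 <= 0)
    stop("all inputs must be positive", call. = FALSE)
  sigma <- length_m / (resistance_ohm * cross_section_m2)
  structure(
    list(resistance = resistance_ohm, length = length_m,
         cross_section = cross_section_m2,
         resistivity = 1 / sigma, conductivity = sigma),
    class = "conductivity_measure")
}

#' @export
print.conductivity_measure <- function(x, ...) {
  cat(sprintf("<conductivity_measure> R = %g Ohm -> sigma = %.3g S/m (rho = %.3g Ohm m)\n",
              x$resistance, x$conductivity, x$resistivity))
  invisible(x)
}

#' Classify electrode contact impedances
#'
#' Maps per-electrode impedances (kOhm) to quality-control classes.
#' The defaults anchor on the two bench observations -- under 10 kOhm
#' is reliably acceptable for EEG, and at or beyond the 50 kOhm meter
#' limit indicates no or very poor contact -- with an intermediate
#' 20 kOhm good/poor boundary. A value equal to a boundary takes the
#' worse class, and a saturated meter reading is `no_contact`
#' regardless of the recorded value. The classes partition `[0, Inf)`.
#'
#' @param impedance_kohm named numeric vector of impedances (kOhm).
#' @param saturated logical vector (recycled) flagging meter-saturated
#'   readings.
#' @param meter_limit meter ceiling in kOhm (default 50).
#' @param thresholds numeric `c(good, acceptable, poor)` upper bounds in
#'   kOhm (default `c(10, 20, 50)`).
#' @return A data.frame with columns `label`, `impedance_kohm`,
#'   `saturated`, `qc_class` (factor: good, acceptable, poor,
#'   no_contact).
#' @export
impedance_qc <- function(impedance_kohm, saturated = FALSE,
                         meter_limit = 50, thresholds = c(10, 20, 50)) {
  if (any(impedance_kohm < 0, na.rm = TRUE))
    stop("impedances must be non-negative", call. = FALSE)
  n <- length(impedance_kohm)
  saturated <- rep_len(as.logical(saturated), n)
  labels <- names(impedance_kohm)
  if (is.null(labels)) labels <- paste0("ch", seq_len(n))
  cls <- ifelse(saturated | impedance_kohm >= min(thresholds[3], meter_limit),
                "no_contact",
                ifelse(impedance_kohm >= thresholds[2], "poor",
                       ifelse(impedance_kohm >= thresholds[1],
                              "acceptable", "good")))
  data.frame(label = labels, impedance_kohm = unname(impedance_kohm),
             saturated = saturated,
             qc_class = factor(cls, levels = c("good", "acceptable",
                                               "poor", "no_contact")),
             stringsAsFactors = FALSE)
}

#' Noise floor of a recording
#'
#' RMS amplitude per channel after band-pass filtering (default
#' 0.3-100 Hz), from an acquisition with no input signal. Wet-contact
#' electrodes are expected close to or under 1 uVrms; failed contacts
#' read hundreds of uVrms.
#'
#' @param rec an `eeg_recording` of at least 2 s.
#' @param band numeric length-2 band (Hz); the upper corner is skipped
#'   when at or above Nyquist.
#' @param order Butterworth order per pass (default 4).
#' @return Named numeric vector of uVrms per channel.
#' @export
noise_floor <- function(rec, band = c(0.3, 100), order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) < 2 * rec$fs)
    stop("need at least 2 s of data", call. = FALSE)
  nyq <- rec$fs / 2
  bh <- signal::butter(order, band[1] / nyq, type = "high")
  bl <- if (band[2] < nyq) signal::butter(order, band[2] / nyq, type = "low")
  rms <- vapply(seq_len(n_channels(rec)), function(i) {
    x <- signal::filtfilt(bh, rec$data[i, ])
    if (!is.null(bl)) x <- signal::filtfilt(bl, x)
    sqrt(mean(x^2))
  }, numeric(1))
  stats::setNames(rms, rec$channel_labels)
}

#' Simulated-signal SNR of a phantom recording
#'
#' Narrowband SNR of the played-back calibration signal (default the
#' 10 Hz alpha-band square wave, neighbor band 5-15 Hz) per channel,
#' with the spectral-peak F-test evaluated at the stated significance
#' level (default 1%).
#'
#' @param rec an `eeg_recording` (at least one Welch window long).
#' @param f0 playback frequency (Hz, default 10).
#' @param band neighbor band (Hz, default `c(5, 15)`).
#' @param alpha significance level (default 0.01).
#' @param window_s,overlap Welch parameters (defaults 8 s, 0.5).
#' @return A data.frame with one row per channel: `channel`, `snr_db`,
#'   `snr_linear`, `f_statistic`, `p_value`, `significant`.
#' @export
simulated_signal_snr <- function(rec, f0 = 10, band = c(5, 15),
                                 alpha = 0.01, window_s = 8, overlap = 0.5) {
  psd <- welch_psd(rec, window_s = window_s, overlap = overlap)
  rows <- lapply(rec$channel_labels, function(ch) {
    r <- narrowband_snr(psd, ch, f0, band, alpha = alpha)
    data.frame(channel = ch, snr_db = r$snr_db, snr_linear = r$snr_linear,
               f_statistic = r$f_statistic, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Phantom integrity trend
#'
#' Day-to-day deltas and percentage change from the first day for a
#' monitored quantity (phantom mass in g, or played-back signal
#' amplitude in mV). No interpolation is performed across missing days.
#'
#' @param day integer-ish vector of measurement days (unique).
#' @param value measured values, same length.
#' @return A data.frame with columns `day`, `value`, `delta` (NA for the
#'   first day), `pct_change_from_first`.
#' @export
integrity_trend <- function(day, value) {
  if (length(day) != length(value) || length(day) < 1)
    stop("`day` and `value` must be equal-length, non-empty", call. = FALSE)
  if (anyDuplicated(day)) stop("duplicate days in series", call. = FALSE)
  ord <- order(day)
  day <- day[ord]; value <- value[ord]
  data.frame(day = day, value = value,
             delta = c(NA_real_, diff(value)),
             pct_change_from_first = 100 * (value - value[1]) / value[1])
}

#' Combined phantom QC report
#'
#' Joins impedance QC, noise floor and simulated-signal SNR into one
#' per-electrode table suitable for CSV export.
#'
#' @param qc output of [impedance_qc()].
#' @param noise named numeric vector from [noise_floor()].
#' @param snr data.frame from [simulated_signal_snr()].
#' @param condition `"wet"` or `"dry"`.
#' @param day testing day index.
#' @return A data.frame with columns `day`, `condition`, `electrode`,
#'   `impedance_kohm`, `saturated`, `noise_uvrms`, `snr_db`, `p`,
#'   `qc_class`.
#' @export
phantom_report <- function(qc, noise = NULL, snr = NULL,
                           condition = c("wet", "dry"), day = 1L) {
  condition <- match.arg(condition)
  out <- data.frame(day = day, condition = condition, electrode = qc$label,
                    impedance_kohm = qc$impedance_kohm,
                    saturated = qc$saturated,
                    noise_uvrms = NA_real_, snr_db = NA_real_, p = NA_real_,
                    qc_class = as.character(qc$qc_class),
                    stringsAsFactors = FALSE)
  if (!is.null(noise))
    out$noise_uvrms <- unname(noise[out$electrode])
  if (!is.null(snr)) {
    i <- match(out$electrode, snr$channel)
    out$snr_db <- snr$snr_db[i]
    out$p <- snr$p_value[i]
  }
  out
}
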