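test_that("Welch segment and STFT frame counts follow the overlap formula", {
  set.seed(6)
  rec <- recording(matrix(rnorm(240 * 500), 1), 500, "Cz")
  psd <- welch_psd(rec)                   # 8 s window, 50%
  expect_equal(psd$segment_count, 59L)    # floor((N-L)/(L/2)) + 1
  expect_equal(psd$freqs[2] - psd$freqs[1], 0.125)
  spg <- stft_spectrogram(rec)            # 2 s window, 50%
  expect_equal(dim(spg$power)[3], 239L)
  expect_equal(spg$times[2] - spg$times[1], 1)  # 1 s hop
  expect_error(welch_psd(recording(matrix(0, 1, 100), 500, "a")),
               "shorter")
})

test_that("Welch PSD integrates to the variance and resolves sinusoid power", {
  set.seed(7)
  rec <- recording(matrix(rnorm(240 * 500), 1), 500, "Cz")
  psd <- welch_psd(rec)
  df <- psd$freqs[2] - psd$freqs[1]
  expect_equal(sum(psd$power[1, ]) * df, 1, tolerance = 0.1)

  a <- 3
  rec2 <- sine_recording(40, amps = a, fs = 500, duration = 240)
  psd2 <- welch_psd(rec2)
  i0 <- which.min(abs(psd2$freqs - 40))
  # band-integrated peak power equals a^2/2
  expect_equal(sum(psd2$power[1, (i0 - 2):(i0 + 2)]) * df, a^2 / 2,
               tolerance = 0.01)
  # stationary sinusoid: time-constant spectrogram peak row
  spg <- stft_spectrogram(rec2)
  row <- spg$power[1, which.min(abs(spg$freqs - 40)), ]
  expect_lt((max(row) - min(row)) / mean(row), 0.1)
  # zero signal -> all-zero power
  spg0 <- stft_spectrogram(recording(matrix(0, 1, 5000), 500, "a"))
  expect_true(all(spg0$power == 0))
})

test_that("narrowband SNR is exact bin arithmetic", {
  # flat spectrum: ratio 1, 0 dB
  fr <- seq(35, 45, by = 0.125)
  p_flat <- manual_psd(fr, rep(7, length(fr)))
  r <- narrowband_snr(p_flat, "ch1", 40, c(35, 45))
  expect_equal(r$snr_linear, 1)
  expect_equal(r$snr_db, 0)
  # P(f0) = 100, all other bins 10 -> ratio 10, 10 dB
  pw <- rep(10, length(fr)); pw[fr == 40] <- 100
  r2 <- narrowband_snr(manual_psd(fr, pw), "ch1", 40, c(35, 45))
  expect_equal(r2$snr_linear, 10)
  expect_equal(r2$snr_db, 10)
  expect_error(narrowband_snr(p_flat, "ch1", 50, c(35, 45)), "contain f0")
})

test_that("narrowband SNR matches brute-force bin enumeration on random spectra", {
  set.seed(8)
  for (k in 1:25) {
    nf <- sample(20:60, 1)
    fr <- seq(30, by = 0.25, length.out = nf)
    pw <- stats::rexp(nf) + 0.01
    f0 <- sample(fr[3:(nf - 2)], 1)
    band <- c(fr[1], fr[nf])
    r <- narrowband_snr(manual_psd(fr, pw), "ch1", f0, band)
    i0 <- which.min(abs(fr - f0))
    expect_equal(r$snr_linear, pw[i0] / mean(pw[-i0]))
  }
})

test_that("snr_db is invariant to scaling the whole spectrum", {
  set.seed(9)
  fr <- seq(35, 45, by = 0.125)
  pw <- stats::rexp(length(fr))
  r1 <- narrowband_snr(manual_psd(fr, pw), "ch1", 40, c(35, 45))
  r2 <- narrowband_snr(manual_psd(fr, pw * 1234.5), "ch1", 40, c(35, 45))
  expect_equal(r1$snr_db, r2$snr_db)
})

test_that("spectral peak F-test agrees with a textbook one-way ANOVA", {
  set.seed(10)
  for (k in 1:25) {
    nseg <- sample(3:8, 1)
    fr <- seq(5, 15, by = 0.5)
    seg <- array(stats::rexp(length(fr) * nseg) + 0.01,
                 dim = c(1, length(fr), nseg))
    psd <- manual_psd(fr, apply(seg[1, , ], 1, mean), seg = seg)
    r <- spectral_peak_ftest(psd, "ch1", 10, c(5, 15))
    i0 <- which.min(abs(fr - 10))
    P <- seg[1, , ]
    reg <- 1e-12 * max(rowMeans(P))
    bf <- brute_anova(log(P[i0, ] + reg),
                      log(as.vector(P[-i0, ]) + reg))
    expect_equal(r$f_statistic, bf$f, tolerance = 1e-9)
    expect_equal(r$p_value, bf$p, tolerance = 1e-9)
  }
})

test_that("degenerate F-test groups are handled by the limit rules", {
  fr <- seq(5, 15, by = 0.5)
  # identical groups -> F ~ 0, p ~ 1
  seg <- array(1, dim = c(1, length(fr), 4))
  psd <- manual_psd(fr, rep(1, length(fr)), seg = seg)
  r <- spectral_peak_ftest(psd, "ch1", 10, c(5, 15))
  expect_equal(r$f_statistic, 0)
  expect_equal(r$p_value, 1)
  # strong peak in noise -> p < 0.05
  set.seed(11)
  seg2 <- array(stats::rexp(length(fr) * 6), dim = c(1, length(fr), 6))
  i0 <- which(fr == 10)
  seg2[1, i0, ] <- seg2[1, i0, ] + 50
  psd2 <- manual_psd(fr, apply(seg2[1, , ], 1, mean), seg = seg2)
  expect_lt(spectral_peak_ftest(psd2, "ch1", 10, c(5, 15))$p_value, 0.05)
})

test_that("alpha modulation obeys ratio identities and reciprocity", {
  set.seed(12)
  # identical conditions -> 0 dB
  rec <- sine_recording(10, amps = 5, fs = 500, duration = 120)
  spg <- stft_spectrogram(rec)
  iv1 <- list(c(0, 60)); iv2 <- list(c(60, 120))
  am <- alpha_modulation(spg, "ch1", iv1, iv2)
  expect_equal(am$ram_db, 0, tolerance = 0.05)
  # power exactly 4x -> 6.02 dB; reciprocity negates the dB value
  dat <- rbind(c(2 * sin(2 * pi * 10 * seq(0, 60, by = 1 / 500)[-1]),
                 1 * sin(2 * pi * 10 * seq(0, 60, by = 1 / 500)[-1])))
  rec2 <- recording(dat, 500, "Oz")
  spg2 <- stft_spectrogram(rec2)
  am2 <- alpha_modulation(spg2, "Oz", list(c(0, 60)), list(c(60, 120)))
  expect_equal(am2$ram_db, 10 * log10(4), tolerance = 0.05)
  am3 <- alpha_modulation(spg2, "Oz", list(c(60, 120)), list(c(0, 60)))
  expect_equal(am3$ram_db, -am2$ram_db, tolerance = 1e-9)
  expect_error(alpha_modulation(spg2, "Oz", list(), list(c(0, 60))),
               "interval")
})

test_that("alpha modulation from two PSDs matches the ratio of band powers", {
  set.seed(13)
  pc <- welch_psd(sine_recording(10, amps = 4, duration = 60))
  po <- welch_psd(sine_recording(10, amps = 2, duration = 60))
  am <- alpha_modulation_psd(pc, po, "ch1")
  expect_equal(am$ram_linear, am$power_closed / am$power_open)
  expect_equal(am$ram_db, 10 * log10(4), tolerance = 0.05)
})

test_that("harmonic scan flags odd square-wave harmonics only", {
  fs <- 500
  tt <- (0:(60 * fs - 1)) / fs
  rec <- recording(matrix(square_wave(tt, 10), 1), fs, "ER8")
  psd <- welch_psd(rec)
  hs <- harmonic_scan(psd, "ER8", 10, 80)
  expect_equal(hs$significant, rep(c(TRUE, FALSE), 4))
  # pure sinusoid: only the fundamental is significant
  set.seed(14)
  rec2 <- recording(matrix(2 * sin(2 * pi * 10 * tt) + rnorm(length(tt)), 1),
                    fs, "Oz")
  hs2 <- harmonic_scan(welch_psd(rec2), "Oz", 10, 80)
  expect_true(hs2$significant[1])
  expect_false(any(hs2$significant[-1]))
  # zero signal: nothing significant
  hs0 <- harmonic_scan(welch_psd(recording(matrix(0, 1, 30 * fs), fs, "a")),
                       "a", 10, 80)
  expect_false(any(hs0$significant))
})

test_that("spectral peak listing returns harmonics in ascending order", {
  fs <- 500
  tt <- (0:(60 * fs - 1)) / fs
  psd <- welch_psd(recording(matrix(square_wave(tt, 10), 1), fs, "ER8"))
  pk <- find_spectral_peaks(psd, "ER8")
  expect_equal(pk$freq[1:4], c(10, 30, 50, 70))
})
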