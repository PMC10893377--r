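test_that("agar recipe reproduces the worked quantities and exact fractions", {
  r <- mixture_agar(700)
  expect_equal(r$component_masses$agar, 30)
  expect_equal(r$component_masses$salt, 4)
  # w = 191 g solves to exactly 8 g and 1 g with no rounding
  r2 <- mixture_agar(191, rounding = "none")
  expect_equal(r2$component_masses$agar, 8)
  expect_equal(r2$component_masses$salt, 1)
  expect_equal(mixture_agar(0)$component_masses$agar, 0)
  expect_error(mixture_agar(-1), "non-negative")
  expect_error(mixture_agar(700, agar_pct = 60, salt_pct = 50), "sum below")
})

test_that("BG recipe follows its closed form (15w/77, 8w/77)", {
  r <- mixture_bg(770)
  expect_equal(r$component_masses$gelatin, 150)
  expect_equal(r$component_masses$salt, 80)
  r2 <- mixture_bg(700)
  expect_equal(r2$component_masses$gelatin, 15 * 700 / 77, tolerance = 1e-12)
  expect_equal(r2$component_masses$salt, 8 * 700 / 77, tolerance = 1e-12)
})

test_that("mixture recipes reproduce their target weight fractions exactly", {
  set.seed(26)
  for (k in 1:20) {
    w <- runif(1, 10, 2000)
    pa <- runif(1, 0.5, 20); ps <- runif(1, 0.1, 10)
    r <- mixture_agar(w, agar_pct = pa, salt_pct = ps, rounding = "none")
    total <- w + r$component_masses$agar + r$component_masses$salt
    expect_equal(r$component_masses$agar / total, pa / 100,
                 tolerance = 1e-12)
    expect_equal(r$component_masses$salt / total, ps / 100,
                 tolerance = 1e-12)
  }
})

test_that("carbon-fiber recipe applies S = V * rho and CF = S x/(100-x)", {
  r <- mixture_cf(700)                         # 1.0%: CF = S/99 -> 8 g
  expect_equal(r$component_masses$carbon_fiber, 8)
  expect_equal(r$exact_masses$silicone, 777)
  # 0.5%: CF = S/199 exactly 1 g at S = 199 g
  r2 <- mixture_cf(199 / 1.11, cf_pct = 0.5, rounding = "none")
  expect_equal(r2$component_masses$carbon_fiber, 1, tolerance = 1e-9)
  expect_equal(mixture_cf(700, cf_pct = 1e-9,
                          rounding = "none")$component_masses$carbon_fiber,
               0, tolerance = 1e-6)
  expect_warning(mixture_cf(700, cf_pct = 1.5), "dense")
  expect_error(mixture_cf(-1), "non-negative")
})

test_that("conductivity applies sigma = L/(R A) and inverts consistently", {
  cm <- conductivity(5000)                     # strip geometry defaults
  expect_equal(cm$conductivity, 0.3)
  expect_equal(cm$resistivity, 1 / 0.3)
  # doubling R halves sigma
  expect_equal(conductivity(10000)$conductivity, 0.15)
  # inverse check against the measured agar value: 0.309 S/m -> R ~ 4854 Ohm
  r_implied <- 0.03 / (0.309 * 2e-5)
  expect_equal(conductivity(r_implied)$conductivity, 0.309,
               tolerance = 1e-12)
  expect_equal(r_implied, 4854.369, tolerance = 1e-3)
  expect_error(conductivity(0), "positive")
})

test_that("impedance QC classes partition [0, Inf) with upward boundaries", {
  qc <- impedance_qc(c(EL1 = 5, EL2 = 10, EL3 = 19.9, EL4 = 20,
                       EL5 = 49.9, EL6 = 50, EL7 = 120))
  expect_equal(as.character(qc$qc_class),
               c("good", "acceptable", "acceptable", "poor", "poor",
                 "no_contact", "no_contact"))
  # saturated flag forces no_contact regardless of the recorded value
  qc2 <- impedance_qc(c(a = 5), saturated = TRUE)
  expect_equal(as.character(qc2$qc_class), "no_contact")
  # partition: every random value maps to exactly one class
  set.seed(27)
  v <- runif(200, 0, 100)
  expect_false(anyNA(impedance_qc(v)$qc_class))
  expect_error(impedance_qc(-1), "non-negative")
})

test_that("noise floor returns band-limited RMS per channel", {
  z <- noise_floor(recording(matrix(0, 2, 5000), 500, c("a", "b")))
  expect_equal(unname(z), c(0, 0))
  # in-band sinusoid of amplitude a -> a/sqrt(2) within 5%
  rec <- sine_recording(10, amps = 4, fs = 250, duration = 20)
  nf <- noise_floor(rec)
  expect_equal(unname(nf), 4 / sqrt(2), tolerance = 0.05)
  expect_error(noise_floor(recording(matrix(0, 1, 100), 500, "a")),
               "2 s")
})

test_that("simulated-signal SNR flags the played-back square wave", {
  ph <- generate_phantom_recording(seed = 28)
  sn <- simulated_signal_snr(ph$recording)
  expect_equal(nrow(sn), 16L)
  expect_true(all(sn$significant))
  expect_true(all(sn$snr_db > 10))
  # halving the amplitude drops a noise-limited channel's SNR as the
  # power-scaling model predicts (~6 dB, less the peak's own leakage
  # into the neighbor average and the noise floor at the target bin)
  ph_lo <- generate_phantom_recording(square_amp_mV = 0.004, seed = 29)
  ph_hi <- generate_phantom_recording(square_amp_mV = 0.008, seed = 29)
  s_lo <- simulated_signal_snr(ph_lo$recording)$snr_db[1]
  s_hi <- simulated_signal_snr(ph_hi$recording)$snr_db[1]
  amp_sine <- function(mv) 4 / pi * mv * 1000 * 0.05  # fundamental of the square
  pred <- function(mv) expected_snr_db(amp_sine(mv), 1, 10, c(5, 15),
                                       window_s = 8, fs = 250)
  expect_equal(s_hi - s_lo, pred(0.008) - pred(0.004), tolerance = 1.5)
  expect_gt(s_hi - s_lo, 3)
  # pure noise: ~0 dB and (essentially) never significant at 1%
  ph0 <- generate_phantom_recording(square_amp_mV = 0, seed = 30)
  s0 <- simulated_signal_snr(ph0$recording)
  expect_lte(sum(s0$significant), 1)
  expect_lt(max(abs(s0$snr_db)), 6)
})

test_that("integrity trend reports deltas and percent change from day 1", {
  tr <- integrity_trend(1:4, c(80, 52, 52, 40))
  expect_equal(tr$delta, c(NA, -28, 0, -12))
  expect_equal(tr$pct_change_from_first[4], -50)
  tr2 <- integrity_trend(1:4, c(855, 851, 850, 845))
  expect_equal(sum(tr2$delta, na.rm = TRUE), -10)
  tr3 <- integrity_trend(1:3, c(7, 7, 7))
  expect_true(all(tr3$delta[-1] == 0))
  expect_error(integrity_trend(c(1, 1), c(2, 3)), "duplicate")
})

test_that("phantom report joins impedance, noise and SNR per electrode", {
  ph <- generate_phantom_recording(contact_quality = c(ER3 = "bad"),
                                   seed = 31)
  noise_rec <- generate_phantom_recording(square_amp_mV = 0,
                                          contact_quality = c(ER3 = "bad"),
                                          seed = 31)
  imp <- stats::setNames(rep(5, 16), ph$recording$channel_labels)
  imp["ER3"] <- 80
  qc <- impedance_qc(imp)
  rep_ <- phantom_report(qc, noise_floor(noise_rec$recording),
                         simulated_signal_snr(ph$recording),
                         condition = "dry", day = 2)
  expect_equal(nrow(rep_), 16L)
  expect_true(all(c("impedance_kohm", "noise_uvrms", "snr_db", "qc_class")
                  %in% names(rep_)))
  er3 <- rep_[rep_$electrode == "ER3", ]
  expect_equal(er3$qc_class, "no_contact")
  expect_gt(er3$noise_uvrms, 10 * rep_[rep_$electrode == "ER4", "noise_uvrms"])
})
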