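test_that("average_erp handles degenerate variance and stays linear", {
  ep <- manual_epochs(matrix(5, 10, 301))
  erp <- average_erp(ep)
  expect_true(all(erp$mean_wave == 5))
  expect_true(all(erp$sig_mask))      # zero variance, nonzero mean
  expect_true(all(erp$p_values == 0))
  ep0 <- manual_epochs(matrix(0, 10, 301))
  expect_false(any(average_erp(ep0)$sig_mask))
  expect_error(average_erp(manual_epochs(matrix(0, 1, 10))), "2 trials")
  # adding a constant to all trials shifts the mean by that constant
  set.seed(15)
  tr <- matrix(rnorm(20 * 50), 20)
  m1 <- average_erp(manual_epochs(tr))$mean_wave
  m2 <- average_erp(manual_epochs(tr + 2.5))$mean_wave
  expect_equal(m2, m1 + 2.5)
})

test_that("average_erp recovers a template within the CLT bound", {
  set.seed(16)
  tm <- seq(-0.1, 0.5, by = 1 / 500)
  tpl <- erp_template(tm, list(N1 = c(0.1, 0.025, -5), P2 = c(0.2, 0.04, 4)))
  sigma <- 2
  trials <- t(replicate(200, tpl + rnorm(length(tm), sd = sigma)))
  erp <- average_erp(manual_epochs(trials))
  expect_lt(max(abs(erp$mean_wave[1, ] - tpl)), 3 * sigma / sqrt(200))
})

test_that("oddball standard selection takes exactly the pre-deviant standards", {
  # sequence S S D S D -> standards used are trials 2 and 4
  set.seed(17)
  tr <- matrix(rnorm(5 * 50), 5)
  ep <- manual_epochs(tr, labels = c("standard", "standard", "deviant",
                                     "standard", "deviant"))
  dw <- oddball_difference(ep)
  expect_equal(dw$standards_used, c(2L, 4L))
  expect_equal(dw$n_deviants, 2L)
  expect_equal(dw$wave[1, ],
               colMeans(tr[c(3, 5), ]) - colMeans(tr[c(2, 4), ]))
  expect_error(oddball_difference(
    manual_epochs(tr, labels = rep("standard", 5))), "deviant")
})

test_that("standard selection matches a brute-force sequence scan on random label orders", {
  set.seed(18)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    labels <- sample(c("standard", "deviant"), n, replace = TRUE,
                     prob = c(0.75, 0.25))
    got <- earval:::standards_before_deviants(labels, "standard", "deviant")
    want <- integer()
    for (i in seq_len(n))                 # brute scan
      if (labels[i] == "deviant" && i > 1 && labels[i - 1] == "standard")
        want <- c(want, i - 1L)
    expect_identical(got, want)
  }
})

test_that("identical standards and deviants give a null difference wave", {
  set.seed(19)
  tm <- seq(-0.1, 0.5, by = 1 / 500)
  tpl <- erp_template(tm, list(P2 = c(0.2, 0.04, 4)))
  trials <- t(replicate(80, tpl + rnorm(length(tm), sd = 1)))
  labels <- rep(c("standard", "deviant"), 40)
  dw <- oddball_difference(manual_epochs(trials, labels = labels))
  expect_lt(max(abs(dw$wave)), 1)
  expect_lt(mean(dw$sig_mask), 0.15)
})

test_that("an injected deviant negativity is recovered in the difference wave", {
  # single channels are noise-limited at ~35 deviants, so recovery is
  # checked on the scalp average (all scalp channels share the template)
  ses <- generate_session(session_spec("aep_oddball", seed = 22))
  scalp <- default_montage()$scalp_labels
  rec <- apply_filter_chain(select_channels(ses$recording, scalp),
                            filter_spec(1, 20))
  ep <- baseline_correct(
    extract_epochs(rec, ses$markers, c("standard", "deviant"), c(-0.1, 0.5)))
  dw <- oddball_difference(ep)
  tm <- dw$times
  delta <- erp_template(tm, ses$truth$deviant_delta)
  i200 <- which.min(abs(tm - 0.2))
  avg <- colMeans(dw$wave)
  g_mean <- mean(ses$truth$cortical_gains[scalp])
  expect_lt(abs(avg[i200] - g_mean * delta[i200]), 1.2)
  expect_lt(avg[i200], -0.5)             # the negativity is there
})

test_that("component metrics find signed extrema with earliest tie-break", {
  tm <- seq(-0.1, 0.5, by = 1 / 500)
  wave <- 15 * exp(-((tm - 0.2)^2) / (2 * 0.03^2))
  erp <- structure(list(times = tm, mean_wave = matrix(wave, 1),
                        channel_labels = "Oz", alpha = 0.05),
                   class = "erp_result")
  cm <- component_metrics(erp, "Oz",
                          data.frame(name = "P2", tmin = 0.15, tmax = 0.3,
                                     polarity = "positive"))
  expect_equal(cm$peak_amplitude, 15)
  expect_equal(cm$peak_latency, 0.2)
  # flat wave: zero amplitude at the window start
  erp0 <- structure(list(times = tm, mean_wave = matrix(0, 1, length(tm)),
                         channel_labels = "Oz", alpha = 0.05),
                    class = "erp_result")
  cm0 <- component_metrics(erp0, "Oz", default_erp_components())
  expect_true(all(cm0$peak_amplitude == 0))
  expect_equal(cm0$peak_latency[cm0$name == "N1"],
               min(tm[tm >= 0.08]))
  expect_error(component_metrics(erp0, "Oz",
                                 data.frame(name = "X", tmin = 2, tmax = 3,
                                            polarity = "positive")),
               "outside")
})

test_that("peak-to-peak between N1 and P2 matches the template sum", {
  tm <- seq(-0.1, 0.5, by = 1 / 500)
  wave <- erp_template(tm, list(N1 = c(0.1, 0.025, -5),
                                P2 = c(0.2, 0.04, 3.9)))
  erp <- structure(list(times = tm, mean_wave = matrix(wave, 1),
                        channel_labels = "Cz", alpha = 0.05),
                   class = "erp_result")
  cm <- component_metrics(erp, "Cz", default_erp_components())
  expect_equal(peak_to_peak(cm, "N1", "P2"), 8.9, tolerance = 0.03)
})

test_that("grand averaging is the unweighted mean of subject means", {
  set.seed(20)
  erps <- lapply(1:3, function(i) {
    tr <- matrix(rnorm(10 * 50, mean = i), 10)
    average_erp(manual_epochs(tr))
  })
  ga <- grand_average(erps)
  expect_equal(ga$mean_wave,
               (erps[[1]]$mean_wave + erps[[2]]$mean_wave +
                  erps[[3]]$mean_wave) / 3)
  expect_equal(ga$n_trials, 3L)
})
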