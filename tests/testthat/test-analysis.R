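test_that("ASSR analysis emits one SNR row per channel of interest", {
  ses <- generate_session(session_spec("assr", seed = 42, duration_s = 60))
  cfg <- analysis_config("assr", reference = "Cz",
                         channels = c("P4", "T8", "ER8"))
  res <- run_analysis(ses$recording, cfg, markers = ses$markers)
  expect_equal(nrow(res), 3L)
  expect_setequal(res$channel, c("P4", "T8", "ER8"))
  expect_true(all(res$metric == "snr_db"))
})

test_that("run_analysis is deterministic and echoes its configuration", {
  dir <- withr::local_tempdir()
  ses <- generate_session(session_spec("assr", seed = 43, duration_s = 60))
  cfg <- analysis_config("assr", reference = "none", channels = "P4")
  r1 <- run_analysis(ses$recording, cfg, markers = ses$markers,
                     out_dir = file.path(dir, "run1"))
  r2 <- run_analysis(ses$recording, cfg, markers = ses$markers,
                     out_dir = file.path(dir, "run2"))
  expect_identical(r1, r2)
  f <- function(run, file) unname(tools::md5sum(file.path(dir, run, file)))
  expect_identical(f("run1", "metrics.csv"), f("run2", "metrics.csv"))
  expect_identical(f("run1", "config.json"), f("run2", "config.json"))
  echoed <- jsonlite::read_json(file.path(dir, "run1", "config.json"),
                                simplifyVector = TRUE)
  expect_equal(echoed$f0, 40)
  expect_equal(echoed$reference, "none")
})

test_that("file-based analysis round-trips through the session format", {
  dir <- withr::local_tempdir()
  ses <- generate_session(session_spec("aep", seed = 44, n_trials = 30))
  write_recording(ses$recording, ses$markers, file.path(dir, "aep"))
  res <- run_analysis(file.path(dir, "aep"),
                      analysis_config("aep", reference = "none",
                                      channels = "Fz"))
  expect_true(all(c("P1_amplitude", "N1_amplitude", "P2_amplitude") %in%
                    res$metric))
  # recovered N1 is negative and P2 positive, as injected
  expect_lt(res$value[res$metric == "N1_amplitude"], 0)
  expect_gt(res$value[res$metric == "P2_amplitude"], 0)
})

test_that("oddball and alpha analyses produce their paradigm metrics", {
  ses <- generate_session(session_spec("aep_oddball", seed = 45,
                                       n_trials = 120))
  res <- run_analysis(ses$recording,
                      analysis_config("mmn", reference = "none",
                                      channels = "Pz"),
                      markers = ses$markers)
  expect_true("MMN_amplitude" %in% res$metric)
  expect_lt(res$value[res$metric == "MMN_amplitude"], 0)

  ses2 <- generate_session(session_spec("alpha_block", seed = 46))
  res2 <- run_analysis(ses2$recording,
                       analysis_config("alpha", reference = "none",
                                       channels = "Oz"),
                       markers = ses2$markers)
  expect_equal(res2$metric, "ram_db")
  expect_equal(res2$value, ses2$truth$injected_ram_db, tolerance = 1)

  res3 <- run_analysis(
    generate_session(session_spec("resting", seed = 47,
                                  duration_s = 60))$recording,
    analysis_config("resting", reference = "none", channels = "Oz"))
  expect_setequal(res3$metric, paste0(c("delta", "theta", "alpha", "beta",
                                        "gamma"), "_power"))
})

test_that("the shipped YAML config reproduces the built-in defaults", {
  cfg <- load_analysis_config("assr", channels = "P4")
  expect_equal(cfg$f0, 40)
  expect_equal(cfg$band, c(35, 45))
  expect_equal(cfg$reference, "Cz")
  cfg2 <- load_analysis_config("p300")
  expect_equal(cfg2$paradigm, "vep_oddball")
  expect_equal(cfg2$latency_correction, 0.021)
  expect_equal(cfg2$epoch_window, c(-0.1, 0.8))
})

test_that("the command-line front end runs over the package functions", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "earval.R", package = "earval")
  out <- system2("Rscript", c(cli, "mixture", "--material", "agar",
                              "--quantity", "700"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("agar: 30 g", out)))
  expect_true(any(grepl("salt: 4 g", out)))
})

test_that("reference comparison ranks a good contact above a bad one", {
  # ER4 good, ER3 bad: referencing to the quiet ER4 must beat the
  # noisy ER3 for the square-wave SNR at the canal electrode ER8.
  # Played amplitude kept in the noise-limited regime (at high
  # amplitude the neighbor average is leakage-dominated and the SNR
  # saturates for any reference).
  ph <- generate_phantom_recording(square_amp_mV = 0.3,
                                   contact_quality = c(ER3 = "bad"),
                                   seed = 48)
  cfg <- analysis_config("assr", reference = "none", channels = "ER8",
                         f0 = 10, band = c(5, 15))
  cmp <- compare_references(ph$recording, cfg, references = c("ER3", "ER4"))
  expect_equal(cmp$reference[1], "ER4")
  expect_lt(cmp$delta_db[cmp$reference == "ER3"],
            cmp$delta_db[cmp$reference == "ER4"])
  # exchangeable contacts (same position gain, both good): deltas ~ 0
  ph2 <- generate_phantom_recording(seed = 48)
  cmp2 <- compare_references(ph2$recording, cfg,
                             references = c("EL4", "ER4"))
  expect_lt(max(abs(cmp2$delta_db)), 1)
  expect_error(compare_references(ph2$recording,
                                  analysis_config("aep", channels = "Fz"),
                                  references = c("Cz", "T8")),
               "spectral")
  expect_error(compare_references(ph2$recording, cfg, references = "ER8"),
               "cannot also be references")
})
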