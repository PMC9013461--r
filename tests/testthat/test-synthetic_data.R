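test_that("protocol has the documented structure", {
  cfg <- eag_config()
  p <- build_protocol(cfg, "2-heptanone")
  expect_equal(nrow(p), 80)  # 40 main + 30 train + 10 control
  expect_equal(as.vector(table(p$block)[c("main", "train", "control")]),
               c(40, 30, 10))
  ## consecutive main-series onsets of one duration differ by exactly 5 s
  main15 <- p$onset_s[p$block == "main" & p$valve_open_s == 0.015]
  expect_equal(diff(main15), rep(5, 9))
  ## train: 30 openings at 100 ms period, last at first + 2.9 s
  trn <- p$onset_s[p$block == "train"]
  expect_equal(length(trn), 30)
  expect_equal(trn[30] - trn[1], 2.9)
  ## train begins 10 s after the last 300-ms main stimulus
  last300 <- max(p$onset_s[p$block == "main" & p$valve_open_s == 0.3])
  expect_equal(trn[1] - last300, 10)
  ## final control block: first odorant, 300 ms, after everything else
  ctrl <- p[p$block == "control", ]
  expect_true(all(ctrl$odorant == "2-heptanone"))
  expect_true(min(ctrl$onset_s) > max(trn))
  ## onsets strictly increasing across the whole protocol
  expect_true(all(diff(p$onset_s) > 0))
})

test_that("protocol validation rejects bad configurations", {
  expect_error(build_protocol(eag_config(), character(0)), "non-empty")
  expect_error(build_protocol(eag_config(isi = 0), "2-heptanone"),
               "positive")
  expect_error(build_protocol(eag_config(), "2-heptanone",
                              durations_ms = c(15, -30)), "positive")
  expect_error(build_protocol(eag_config(), "unknown-odorant"), "kinetics")
})

test_that("concentration trace follows the first-order step response", {
  ## no valve opening -> all zero
  p0 <- data.frame(onset_s = numeric(0), valve_open_s = numeric(0),
                   odorant = character(0))
  expect_equal(concentration_trace(p0, list(rise = 0.1, decay = 0.3),
                                   1000, t_end = 1), numeric(1000))
  ## closed form: 300 ms opening, rise tau 0.1 -> peak 1 - exp(-3)
  p1 <- data.frame(onset_s = 1, valve_open_s = 0.3, odorant = "x")
  co <- concentration_trace(p1, list(rise = 0.1, decay = 0.3), 1000,
                            t_end = 3)
  expect_equal(max(co), 1 - exp(-0.3 / 0.1), tolerance = 1e-6)
  expect_true(all(co >= 0 & co <= 1))
  ## peak monotone in valve-open duration for any rise tau
  for (tau in c(0.02, 0.065, 0.3)) {
    peaks <- vapply(c(0.015, 0.03, 0.15, 0.3), function(d) {
      p <- data.frame(onset_s = 1, valve_open_s = d, odorant = "x")
      max(concentration_trace(p, list(rise = tau, decay = 0.3), 1000,
                              t_end = 2))
    }, numeric(1))
    expect_true(all(diff(peaks) > 0))
  }
  expect_error(concentration_trace(p1, list(rise = 0, decay = 0.3), 1000),
               "positive")
})

test_that("recordings are deterministic and respect degenerate settings", {
  cfg <- tiny_cfg(noise_sd = 0, drift_amplitude = 0,
                  ecotype_effects = list(amplitude_ratio = 1,
                                         onset_delay = 0, offset_delay = 0))
  p <- build_protocol(cfg, "2-heptanone")
  fw <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "full-winged"))
  wr <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "wing-reduced"))
  ## symmetry: no ecotype effects + no noise -> identical traces
  expect_identical(fw$voltage, wr$voltage)
  ## determinism: same config + seed -> bit-identical
  fw2 <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "full-winged"))
  expect_identical(fw$voltage, fw2$voltage)
  ## gain 0 -> flat zero trace
  z <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "full-winged",
                                       gain = 0))
  expect_equal(z$voltage, numeric(length(z$voltage)))
})

test_that("amplitude ratio scales the response linearly", {
  cfg <- tiny_cfg(noise_sd = 0, drift_amplitude = 0,
                  ecotype_effects = list(amplitude_ratio = 0.5,
                                         onset_delay = 0, offset_delay = 0))
  p <- build_protocol(cfg, "2-heptanone")
  fw <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "full-winged"))
  wr <- generate_recording(cfg, p, list(antenna_id = "a", ecotype = "wing-reduced"))
  expect_equal(wr$voltage, 0.5 * fw$voltage, tolerance = 1e-12)
})

test_that("cohorts carry ground truth and are reproducible", {
  cfg <- tiny_cfg(ecotype_effects = list(amplitude_ratio = 0.5,
                                         onset_delay = 0.05,
                                         offset_delay = 0.05))
  ch1 <- generate_cohort(cfg, odorants = "2-heptanone")
  ch2 <- generate_cohort(cfg, odorants = "2-heptanone")
  expect_length(ch1$recordings, 4)
  expect_identical(ch1$recordings[["fw01"]]$voltage,
                   ch2$recordings[["fw01"]]$voltage)
  expect_equal(unique(ch1$ground_truth$true_log2_ratio), -1)  # log2(0.5)
  expect_error(generate_cohort(eag_config(n_antennae = 0)))
})

test_that("zero between-antenna SD gives identical same-ecotype antennae", {
  cfg <- tiny_cfg(between_antenna_sd = 0, noise_sd = 0, drift_amplitude = 0)
  ch <- generate_cohort(cfg, odorants = "2-heptanone")
  expect_identical(ch$recordings[["fw01"]]$voltage,
                   ch$recordings[["fw02"]]$voltage)
})

test_that("response peak is non-decreasing in valve-open duration", {
  cfg <- tiny_cfg(noise_sd = 0, drift_amplitude = 0)
  p <- build_protocol(cfg, "2-heptanone")
  rec <- generate_recording(cfg, p, list(antenna_id = "a",
                                         ecotype = "wing-reduced"))
  pp <- preprocess_recording(rec)
  peaks <- vapply(c("15", "30", "150", "300"), function(d)
    max(pp$stimuli[[paste0("2-heptanone/", d)]]$voltage), numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("config invariants are enforced", {
  expect_error(eag_config(sampling_rate = 0), "positive")
  expect_error(eag_config(noise_sd = -1))
  expect_error(eag_config(artifact_probability = 1.5), "\\[0, 1\\]")
  expect_error(eag_config(antenna_kinetics = list(latency = 0.1, rise = -1,
                                                  decay = 0.5, gain = 1)))
})

test_that("metrics-level simulation reflects the configured effects", {
  cfg <- eag_config(n_antennae = 50, between_antenna_sd = 0.2,
                    log2_residual_sd = 0.1,
                    ecotype_effects = list(amplitude_ratio = 0.5,
                                           onset_delay = 0.05,
                                           offset_delay = 0.05))
  tab <- simulate_metrics_table(cfg, seed = 5)
  expect_equal(nrow(tab), 2 * 50 * 4)
  agg <- tapply(log2(tab$strength_mV), tab$ecotype, mean)
  expect_equal(unname(agg["wing-reduced"] - agg["full-winged"]), -1,
               tolerance = 0.15)
  on <- tapply(tab$onset_s, tab$ecotype, median)
  expect_gt(on[["wing-reduced"]], on[["full-winged"]])
})
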