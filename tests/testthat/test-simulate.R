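test_that("with every generative term off, all samples equal the baseline", {
  sch <- build_protocol(25, n_repetitions = 1)
  st <- simulate_trace(sim_params_noiseless(baseline_iop = 16.5,
                                            offset_table = default_offset_table() * 0),
                       sch, seed = 1)
  expect_true(all(st$trace$iop == 16.5))
})

test_that("plateau offsets and eyelid offset appear in the truth table; PRIMARY is 0", {
  sch <- build_protocol(25, n_repetitions = 1, eyelid = TRUE)
  st <- simulate_trace(sim_params_noiseless(spike_amp = 3,
                                            eyelid_spike_amp = 4),
                       sch, seed = 1)
  tr <- st$truth
  expect_true(all(tr$delta_true[tr$label == "PRIMARY"] == 0))
  expect_equal(tr$delta_true[tr$label == "S"][1],
               default_offset_table()["S", "25"])
  expect_true(all(tr$delta_true[tr$label == "CLOSED"] == -2.1))
  # closure transient always positive, gaze transient signed toward plateau
  expect_true(all(tr$spike[tr$label == "CLOSED"] > 0))
  expect_lt(tr$spike[tr$label == "IN"][1], 0)
})

test_that("ocular pulse alone gives the configured peak-to-trough within a plateau", {
  sch <- two_epoch_schedule()
  st <- simulate_trace(sim_params_noiseless(pulse_amp = 2, rate_jitter = 0),
                       sch, seed = 1)
  w <- st$trace$iop[st$trace$time_s >= 14 & st$trace$time_s < 22]
  ptt <- max(w) - min(w)
  # 9 Hz sampling of a 1.2 Hz sinusoid hits phases 24 degrees apart, so the
  # sampled peak-to-trough is within 2*(1-cos(12 deg)) of the true 2.0
  expect_gte(ptt, 2 * cos(12 * pi / 180) - 1e-9)
  expect_lte(ptt, 2 + 1e-9)
})

test_that("pulse term has zero mean over an integer number of beat periods", {
  sch <- two_epoch_schedule()
  st <- simulate_trace(sim_params_noiseless(pulse_amp = 2, rate_jitter = 0,
                                            baseline_iop = 0),
                       sch, seed = 1)
  # 15 consecutive 9 Hz samples span exactly 2 beats at 1.2 Hz
  expect_equal(mean(st$trace$iop[1:15]), 0, tolerance = 1e-12)
})

test_that("last-2-s plateau estimate recovers the configured offset (generator law of large numbers)", {
  sch <- two_epoch_schedule("S", 25)
  p <- sim_params(drift_sd = 0)          # random walk excluded: unbounded
  st <- simulate_trace(p, sch, seed = 17)
  w <- extract_windows(st$trace, sch)
  est <- w$last2_mean[w$label == "S"] - w$mean_iop[w$label == "PRIMARY"]
  n <- w$last2_n[w$label == "S"]
  expect_equal(est, p$offset_table["S", "25"],
               tolerance = 3 * p$noise_sd / sqrt(n) + 0.1)
})

test_that("saccadic transient decays below the analytic bound by the final window", {
  sch <- two_epoch_schedule("S", 25)
  p <- sim_params_noiseless(spike_amp = 3, spike_tau = 2.5)
  st <- simulate_trace(p, sch, seed = 1)
  w <- extract_windows(st$trace, sch)
  resid <- abs((w$tw_final_mean[2] - w$mean_iop[1]) - p$offset_table["S", "25"])
  expect_lt(resid, 3 * exp(-6 / 2.5))
  expect_gt(resid, 0)                    # the transient is actually there
})

test_that("artifact injection: identity, dropout counting, cough amplitude, merge warning", {
  sch <- two_epoch_schedule()
  st <- simulate_trace(sim_params_noiseless(), sch, seed = 1)
  expect_identical(inject_artifacts(st$trace)$iop, st$trace$iop)

  # 5-s dropout inside the 12-s gaze epoch leaves < 60% of expected samples
  tr2 <- inject_artifacts(st$trace, dropout_spans = data.frame(
    start_s = 14, end_s = 19))
  w2 <- extract_windows(tr2, sch)
  expect_lt(w2$n_obs[2] / w2$n_expected[2], 0.6)

  # cough at epoch midpoint with amplitude 10 towers over the plateau
  tr3 <- inject_artifacts(st$trace, cough_times = 18, cough_amp = 10)
  plateau <- max(st$trace$iop[st$trace$time_s >= 14])
  expect_gte(max(tr3$iop[tr3$time_s >= 14]), plateau + 8)

  expect_warning(inject_artifacts(st$trace, dropout_spans = data.frame(
    start_s = c(2, 3), end_s = c(4, 5))), "merged")
})

test_that("identical master seeds give bit-identical cohorts", {
  spec <- cohort_spec(n_patients = 2, n_repetitions = 1, eyelid_n = 1,
                      eccentricities = 25, seed = 9)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1[[1]]$trace$iop, c2[[1]]$trace$iop)
  expect_identical(c1[[2]]$trace$iop, c2[[2]]$trace$iop)
  # different seed changes the draw
  spec$seed <- 10L
  c3 <- simulate_cohort(spec)
  expect_false(identical(c1[[1]]$trace$iop, c3[[1]]$trace$iop))
})

test_that("zero dispersion shares one offset table; configured dispersion is recovered at n = 1000", {
  spec0 <- noiseless_cohort_spec(n_patients = 3)
  pars <- lapply(1:3, function(i) draw_patient_params(spec0, sim_params(), i))
  expect_identical(pars[[1]]$offset_table, pars[[2]]$offset_table)

  spec <- cohort_spec(seed = 4)          # default dispersion: SD 4.908 at S/25
  sd_target <- default_offset_dispersion()["S", "25"]
  draws <- vapply(1:1000, function(i)
    draw_patient_params(spec, sim_params(), i)$offset_table["S", "25"], 0)
  expect_equal(sd(draws), sd_target, tolerance = 0.1 * sd_target)
})

test_that("derived child seeds are valid integers and distinct across streams", {
  s <- vapply(0:200, function(i) derive_seed(1, i), 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
  expect_identical(derive_seed(1, 5), derive_seed(1, 5))
  expect_false(derive_seed(1, 5) == derive_seed(2, 5))
})
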