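test_that("a 12-s epoch trimmed by 2 s holds exactly the 72 on-grid samples of [2,10)", {
  # at exact 9 Hz from t = 0, samples k/9 in [2, 10) are k = 18..89
  sch <- epoch_schedule(data.frame(
    label = "PRIMARY", eccentricity_deg = 0, start_s = 0, end_s = 12,
    repetition = 1))
  tr <- grid_trace(12, function(t) rep(16, length(t)))
  w <- extract_windows(tr, sch)
  expect_identical(w$n_expected, 72L)
  expect_identical(w$n_obs, 72L)
  expect_equal(w$mean_iop, 16)
  expect_equal(w$tw_initial_mean, 16)
  expect_equal(w$last2_mean, 16)
})

test_that("epochs shorter than twice the trim are rejected by name", {
  sch <- epoch_schedule(data.frame(
    label = "PRIMARY", eccentricity_deg = 0, start_s = 0, end_s = 3,
    repetition = 1))
  tr <- grid_trace(3, function(t) rep(16, length(t)))
  expect_error(extract_windows(tr, sch, trim_s = 2), "shorter than twice")
})

test_that("QC flags windows by retained fraction and artifact overlap", {
  sch <- two_epoch_schedule()
  tr <- grid_trace(24, function(t) rep(16, length(t)))
  w <- extract_windows(tr, sch)
  expect_true(all(qc_filter(w)$qc_pass))

  # drop 70% of the gaze window's samples
  keep <- !(tr$time_s >= 14 & tr$time_s < 19.6)
  w2 <- extract_windows(iop_trace(tr$time_s[keep], tr$iop[keep]), sch)
  q2 <- qc_filter(w2)
  expect_false(q2$qc_pass[2])
  expect_true(q2$qc_pass[1])

  # declared cough span overlapping the window
  q3 <- qc_filter(w, artifact_spans = data.frame(start_s = 17, end_s = 17.5))
  expect_false(q3$qc_pass[2])

  # wholesale repetition exclusion
  q4 <- qc_filter(w2, drop_repetition = TRUE)
  expect_false(any(q4$qc_pass))
})

test_that("delta IOP is the arithmetic difference of gaze and preceding baseline means", {
  sch <- two_epoch_schedule("S", 25)
  tr <- grid_trace(24, function(t) ifelse(t < 12, 16, 18))
  rec <- compute_delta_iop(extract_windows(tr, sch))
  expect_equal(rec$delta_iop, 2)
  expect_equal(rec$gaze_mean - rec$baseline_mean, rec$delta_iop)

  # identical levels give exactly zero
  tr0 <- grid_trace(24, function(t) rep(16, length(t)))
  expect_equal(compute_delta_iop(extract_windows(tr0, sch))$delta_iop, 0)
})

test_that("a gaze window without a preceding baseline raises an error", {
  sch <- two_epoch_schedule()
  tr <- grid_trace(24, function(t) rep(16, length(t)))
  w <- extract_windows(tr, sch)
  expect_error(compute_delta_iop(w[2, ]), "preceding PRIMARY")
})

test_that("noiseless simulated response equals the configured offset exactly", {
  sch <- two_epoch_schedule("S", 25)
  ot <- default_offset_table()
  st <- simulate_trace(sim_params_noiseless(offset_table = ot), sch, seed = 1)
  rec <- compute_delta_iop(extract_windows(st$trace, sch))
  expect_equal(rec$delta_iop, ot["S", "25"], tolerance = 1e-12)
})

test_that("time-window statistics match the enumerated ramp oracle", {
  # IOP(t) = t - 12 during the gaze epoch, 0 during baseline, on the 9 Hz
  # grid: TW_initial = mean(k/9, k=18..35) = 26.5/9, TW_final = 80.5/9
  sch <- two_epoch_schedule("S", 25)
  tr <- grid_trace(24, function(t) ifelse(t < 12, 0, t - 12))
  tw <- compute_time_windows(extract_windows(tr, sch))
  expect_equal(tw$tw_initial, 26.5 / 9, tolerance = 1e-12)
  expect_equal(tw$tw_final, 80.5 / 9, tolerance = 1e-12)
  expect_equal(tw$d_delta_iop, -6, tolerance = 1e-12)

  # flat plateau: no within-epoch drift
  tr0 <- grid_trace(24, function(t) ifelse(t < 12, 16, 18))
  expect_equal(compute_time_windows(extract_windows(tr0, sch))$d_delta_iop, 0)
})

test_that("d_delta_iop is invariant to adding a constant to the whole trace", {
  sch <- two_epoch_schedule("S", 25)
  st <- simulate_trace(sim_params(), sch, seed = 3)
  tw1 <- compute_time_windows(extract_windows(st$trace, sch))
  shifted <- iop_trace(st$trace$time_s, st$trace$iop + 7.3)
  tw2 <- compute_time_windows(extract_windows(shifted, sch))
  expect_equal(tw2$d_delta_iop, tw1$d_delta_iop, tolerance = 1e-10)
})

test_that("a decaying positive transient yields 0 < d_delta_iop < spike amplitude", {
  sch <- two_epoch_schedule("S", 25)
  st <- simulate_trace(sim_params_noiseless(spike_amp = 3, spike_tau = 2.5),
                       sch, seed = 1)
  tw <- compute_time_windows(extract_windows(st$trace, sch))
  expect_gt(tw$d_delta_iop, 0)
  expect_lt(tw$d_delta_iop, 3)
})

test_that("eyelid responses use the last 2 s of the closure epoch", {
  sch <- epoch_schedule(data.frame(
    label = c("PRIMARY", "CLOSED"), eccentricity_deg = 0,
    start_s = c(0, 12), end_s = c(12, 22), repetition = 1))
  # closure: initial 4 mm Hg transient decaying with tau = 1 s over offset -2
  tr <- grid_trace(22, function(t)
    ifelse(t < 12, 16, 14 + 4 * exp(-(t - 12) / 1)))
  ey <- compute_eyelid_deltas(extract_windows(tr, sch))
  expect_equal(nrow(ey), 1L)
  # contamination of the last-2-s window by the transient is < 4 e^-8
  expect_equal(ey$delta_iop, -2, tolerance = 4 * exp(-8))
  expect_lt(abs(ey$delta_iop + 2), 0.01)

  # closure identical to baseline gives zero
  tr0 <- grid_trace(22, function(t) rep(16, length(t)))
  expect_equal(compute_eyelid_deltas(extract_windows(tr0, sch))$delta_iop, 0)

  # absence of CLOSED epochs warns and returns empty
  sch2 <- two_epoch_schedule()
  tr2 <- grid_trace(24, function(t) rep(16, length(t)))
  expect_warning(out <- compute_eyelid_deltas(extract_windows(tr2, sch2)),
                 "no CLOSED")
  expect_identical(nrow(out), 0L)
})

test_that("group aggregation averages repetitions per patient, then patients; control S excluded", {
  spec <- noiseless_cohort_spec(n_patients = 3, n_repetitions = 2,
                                eyelid_n = 0, eccentricities = 25)
  cohort <- simulate_cohort(spec, sim_params_noiseless())
  rec <- NULL
  for (p in cohort)
    rec <- rbind(rec, compute_delta_iop(extract_windows(p$trace, p$schedule)))
  # the closing control S is flagged once per block
  expect_identical(sum(rec$is_control),
                   as.integer(3 * 2))          # patients x repetitions
  g <- aggregate_group(rec)
  ot <- default_offset_table()
  gd <- g[g$direction != "Overall", ]
  expect_equal(gd$delta_mean, unname(ot[gd$direction, "25"]),
               tolerance = 1e-12)
  # dispersion 0, noise off: SEM exactly 0
  expect_true(all(gd$delta_sem < 1e-12))
  # Overall row equals the mean of the eight per-direction means
  expect_equal(g$delta_mean[g$direction == "Overall"],
               mean(gd$delta_mean), tolerance = 1e-12)
})

test_that("single-patient aggregation reports SEM as missing", {
  spec <- noiseless_cohort_spec(n_patients = 1, n_repetitions = 1,
                                eyelid_n = 0, eccentricities = 25)
  cohort <- simulate_cohort(spec, sim_params_noiseless())
  rec <- compute_delta_iop(extract_windows(cohort[[1]]$trace,
                                           cohort[[1]]$schedule))
  g <- aggregate_group(rec)
  expect_true(all(is.na(g$delta_sem)))
})
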