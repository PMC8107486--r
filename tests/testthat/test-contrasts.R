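# records-table constructor for contrast-level tests
make_records <- function(patient_id, direction, eccentricity_deg, repetition,
                         delta_iop, is_control = FALSE) {
  data.frame(patient_id = patient_id, direction = direction,
             eccentricity_deg = eccentricity_deg, repetition = repetition,
             ordinal = seq_along(delta_iop), baseline_mean = 16,
             gaze_mean = 16 + delta_iop, delta_iop = delta_iop,
             qc_pass = TRUE, is_control = is_control,
             stringsAsFactors = FALSE)
}

test_that("vertical composites average their three constituents", {
  dirs <- c("SN", "S", "ST", "IT", "I", "IN")
  r <- make_records("P01", dirs, 25, 1, c(1, 2, 3, -1, -2, -3))
  comp <- vertical_composites(r)
  expect_equal(comp$snt, 2)
  expect_equal(comp$int, -2)
  expect_true(comp$complete)

  # equal inputs give the common value
  r2 <- make_records("P01", dirs, 25, 1, rep(0.7, 6))
  expect_equal(vertical_composites(r2)$snt, 0.7)

  # group-level SNT at 25 degrees from the default offsets: mean(2.9, 4.4, 2.9)
  ot <- default_offset_table()
  r3 <- make_records("P01", dirs, 25, 1,
                     unname(ot[dirs, "25"]))
  expect_equal(vertical_composites(r3)$snt, 3.4, tolerance = 1e-12)

  # missing constituent is flagged, not dropped
  r4 <- make_records("P01", dirs[-1], 25, 1, c(2, 3, -1, -2, -3))
  comp4 <- vertical_composites(r4)
  expect_false(comp4$complete)
  expect_true(is.na(comp4$snt))
  expect_false(is.na(comp4$int))
})

test_that("per-patient extreme-direction contrast counts the separable patients", {
  set.seed(2)
  recs <- NULL
  for (i in 1:11) {
    sep <- i <= 8                        # 8 separated, 3 with equal offsets
    if (sep) {
      s_vals <- 4 + rnorm(3, 0, 0.05)
      in_vals <- -1.6 + rnorm(3, 0, 0.05)
    } else {
      # identical gaze responses in both directions within each repetition
      s_vals <- in_vals <- 1 + rnorm(3, 0, 0.05)
    }
    recs <- rbind(recs,
                  make_records(sprintf("P%02d", i), rep("S", 3), 25, 1:3,
                               s_vals),
                  make_records(sprintf("P%02d", i), rep("IN", 3), 25, 1:3,
                               in_vals))
  }
  res <- individual_extreme_contrast(recs)
  expect_identical(attr(res, "n_significant"), 8L)
  expect_true(all(res$df == 2L, na.rm = TRUE))

  # identical values give t = 0, p = 1
  same <- rbind(make_records("P01", rep("S", 3), 25, 1:3, c(1, 2, 3)),
                make_records("P01", rep("IN", 3), 25, 1:3, c(1, 2, 3)))
  res0 <- individual_extreme_contrast(same)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  # a patient with a single repetition is skipped with a flag
  one <- rbind(make_records("P01", "S", 25, 1, 2),
               make_records("P01", "IN", 25, 1, -1))
  expect_true(individual_extreme_contrast(one)$skipped)
})

test_that("internal-control test detects an injected response decline and not its absence", {
  mk <- function(first, ctrl) {
    rbind(
      make_records(sprintf("P%02d", 1:9), "S", 25, 1, first),
      make_records(sprintf("P%02d", 1:9), "S", 25, 1, ctrl,
                   is_control = TRUE))
  }
  set.seed(14)
  base <- 4 + rnorm(9, 0, 0.3)
  # identical first/closing plateaus: exactly no sequential effect
  stable <- internal_control_test(mk(base, base))
  expect_equal(stable$estimate, 0)
  expect_equal(stable$p, 1)
  # decaying response gain: the closing control sits 1 mm Hg lower
  decline <- internal_control_test(mk(base, base - 1 + rnorm(9, 0, 0.1)))
  expect_gt(decline$estimate, 0.5)
  expect_lt(decline$p, 0.01)
  expect_identical(decline$df, 8L)

  expect_error(internal_control_test(make_records("P01", "S", 25, 1, 1)),
               "control")
})

test_that("eyelid vs downgaze: identity gives t = 0; generator oracle recovers the configured contrast", {
  ey <- data.frame(patient_id = paste0("P0", 1:5), delta_iop = c(-2, -1, -3, -2, -1.5),
                   n_repetitions = 4L)
  comp <- data.frame(patient_id = paste0("P0", 1:5), eccentricity_deg = 25,
                     snt = 1, int = ey$delta_iop, complete = TRUE)
  tt <- eyelid_vs_downgaze(ey, composites = comp)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)

  # mismatched patient subsets are named
  comp_bad <- comp[-1, ]
  expect_error(eyelid_vs_downgaze(ey, composites = comp_bad), "P01")

  # low-noise simulated cohort: estimate = eyelid offset minus the true
  # 25-degree INT composite, mean(0.14, -0.55, -1.6) = -0.67
  spec <- noiseless_cohort_spec(n_patients = 9, n_repetitions = 1,
                                eyelid_n = 9, eccentricities = 25, seed = 6)
  p <- sim_params(noise_sd = 0.05, drift_sd = 0, pulse_amp = 0,
                  spike_amp = 0, eyelid_spike_amp = 0, rate_jitter = 0)
  cohort <- simulate_cohort(spec, p)
  w <- NULL
  for (pt in cohort)
    w <- rbind(w, extract_windows(pt$trace, pt$schedule))
  w <- qc_filter(w)
  tw <- compute_time_windows(w)
  ey2 <- eyelid_patient_means(compute_eyelid_deltas(w))
  comp2 <- vertical_composites(tw, value = "tw_final")
  tt2 <- eyelid_vs_downgaze(ey2, composites = comp2)
  true_contrast <- p$eyelid_offset - mean(p$offset_table[c("IT", "I", "IN"), "25"])
  expect_equal(tt2$estimate, true_contrast, tolerance = 0.1)
  expect_lt(tt2$p, 0.05)
  expect_identical(tt2$df, 8L)
})
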