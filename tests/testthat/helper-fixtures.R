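# Shared fixtures: tiny schedules and analytically defined traces built on
# the exact 9 Hz grid, so expected window contents can be enumerated.

grid_trace <- function(t_end, f, rate = 9, patient_id = "P01") {
  k <- 0:(ceiling(t_end * rate) - 1L)
  tt <- k / rate
  tt <- tt[tt < t_end]
  iop_trace(tt, f(tt), patient_id = patient_id, nominal_rate = rate)
}

# PRIMARY [0,12) followed by a single gaze epoch [12,24)
two_epoch_schedule <- function(label = "S", ecc = 25, patient_id = "P01") {
  epoch_schedule(data.frame(
    label = c("PRIMARY", label), eccentricity_deg = c(0, ecc),
    start_s = c(0, 12), end_s = c(12, 24), repetition = 1),
    patient_id = patient_id)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# Small deterministic cohort configurations used across test files
noiseless_cohort_spec <- function(...) {
  args <- list(baseline_sd = 0, delta_sd = 0, eyelid_sd = 0, eyelid_n = 0,
               seed = 1)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}
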