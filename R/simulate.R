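#' Default gaze-offset table (mm Hg)
#'
#' Additive plateau IOP offsets relative to primary gaze for the eight gaze
#' directions at 10, 20 and 25 degrees of eccentricity. These defaults encode
#' the characteristic group-level pattern of gaze-dependent IOP seen in
#' implanted-sensor telemetry: IOP rises in upgaze (up to about +4.4 mm Hg at
#' 25 degrees superior), rises moderately temporally, and falls in downgaze
#' and nasally (down to about -1.6 mm Hg at 25 degrees inferonasal).
#'
#' @return An 8 x 3 numeric matrix, rows named by gaze direction
#'   (S, ST, T, IT, I, IN, N, SN), columns by eccentricity ("10", "20", "25").
#' @export
default_offset_table <- function() {
  matrix(c(
    #  10     20     25
     1.10,  3.90,  4.40,   # S
     0.87,  2.60,  2.90,   # ST
     0.60,  1.10,  1.20,   # T
     0.33,  0.47,  0.14,   # IT
    -0.31, -0.45, -0.55,   # I
    -0.71, -1.10, -1.60,   # IN
    -0.18, -0.71, -0.51,   # N
     0.66,  1.90,  2.90),  # SN
    nrow = 8, byrow = TRUE,
    dimnames = list(GAZE_LABELS, c("10", "20", "25")))
}

#' Default between-patient dispersion of the gaze offsets (mm Hg SD)
#'
#' Between-patient standard deviations of the per-condition plateau offsets,
#' matching the spread implied by cohort-level standard errors in an
#' 11-patient cohort (SD = SEM x sqrt(11)); e.g. about 4.9 mm Hg SD for the
#' 25-degree superior response.
#'
#' @return An 8 x 3 numeric matrix shaped like [default_offset_table()].
#' @export
default_offset_dispersion <- function() {
  sem <- matrix(c(
    0.61, 1.38, 1.48,    # S
    0.28, 0.70, 0.94,    # ST
    0.083, 0.36, 0.27,   # T
    0.14, 0.12, 0.27,    # IT
    0.17, 0.23, 0.31,    # I
    0.16, 0.18, 0.23,    # IN
    0.17, 0.47, 0.67,    # N
    0.42, 0.88, 1.40),   # SN
    nrow = 8, byrow = TRUE,
    dimnames = list(GAZE_LABELS, c("10", "20", "25")))
  sem * sqrt(11)
}

#' Generative parameters of the telemetry simulator
#'
#' The simulated signal is the sum of a patient baseline, a per-epoch plateau
#' offset, a saccadic spike-then-decay transient at every condition change, a
#' heart-rate-locked sinusoidal ocular pulse, a slow random-walk drift and
#' white measurement noise:
#' \deqn{IOP(t) = IOP_0 + \delta(epoch) + A e^{-(t - t_{on})/\tau} +
#'   \frac{OPA}{2}\sin(2\pi f_{HR} t) + drift(t) + \epsilon(t)}
#' The spike amplitude `A` is signed toward the new plateau for gaze changes
#' (overshoot) and always positive for eyelid closure, whose plateau is
#' `eyelid_offset`.
#'
#' @param baseline_iop Baseline IOP at primary gaze (mm Hg, default 16.5).
#' @param offset_table 8 x 3 matrix of plateau offsets delta(direction,
#'   eccentricity) in mm Hg; default [default_offset_table()]. Primary gaze
#'   has offset 0 by construction.
#' @param pulse_amp Ocular pulse amplitude, peak-to-trough (mm Hg, default 2).
#' @param heart_rate Heart rate in Hz (default 1.2).
#' @param spike_amp Saccadic transient amplitude (mm Hg, default 3); a free
#'   parameter of the generator, not an empirically fixed value.
#' @param spike_tau Exponential decay constant of the saccadic transient
#'   (s, default 2.5).
#' @param eyelid_spike_amp Transient amplitude on eyelid closure (mm Hg,
#'   default 4), always positive.
#' @param eyelid_offset Steady-state IOP change under closure (mm Hg,
#'   default -2.1).
#' @param eyelid_tau Decay constant of the closure transient (s, default 2).
#' @param noise_sd White measurement noise SD (mm Hg, default 0.3).
#' @param drift_sd Per-sample SD of the random-walk drift (mm Hg,
#'   default 0.05).
#' @param rate_jitter Fractional timestamp jitter; each sample time is
#'   `(k + U(-rate_jitter, rate_jitter)) / rate` (default 0.05; must be
#'   < 0.5 to keep timestamps strictly increasing).
#' @param rate Nominal sampling rate in Hz (default 9).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(baseline_iop = 16.5,
                       offset_table = default_offset_table(),
                       pulse_amp = 2, heart_rate = 1.2,
                       spike_amp = 3, spike_tau = 2.5,
                       eyelid_spike_amp = 4, eyelid_offset = -2.1,
                       eyelid_tau = 2,
                       noise_sd = 0.3, drift_sd = 0.05,
                       rate_jitter = 0.05, rate = 9) {
  offset_table <- as.matrix(offset_table)
  if (!all(GAZE_LABELS %in% rownames(offset_table)))
    stop("offset_table must have rows for all 8 gaze directions")
  if (ncol(offset_table) < 1L || is.null(colnames(offset_table)))
    stop("offset_table must have eccentricity column names")
  if (pulse_amp < 0 || spike_tau <= 0 || eyelid_tau <= 0 || noise_sd < 0 ||
      drift_sd < 0 || heart_rate <= 0 || rate <= 0)
    stop("pulse_amp, noise_sd, drift_sd must be >= 0; rates and taus > 0")
  if (rate_jitter < 0 || rate_jitter >= 0.5)
    stop("rate_jitter must be in [0, 0.5)")
  structure(list(
    baseline_iop = baseline_iop, offset_table = offset_table,
    pulse_amp = pulse_amp, heart_rate = heart_rate,
    spike_amp = spike_amp, spike_tau = spike_tau,
    eyelid_spike_amp = eyelid_spike_amp, eyelid_offset = eyelid_offset,
    eyelid_tau = eyelid_tau, noise_sd = noise_sd, drift_sd = drift_sd,
    rate_jitter = rate_jitter, rate = rate), class = "sim_params")
}

#' Deterministic noise-free parameter set
#'
#' Convenience wrapper around [sim_params()] with every stochastic and
#' transient term switched off; the simulated signal is then exactly
#' baseline + plateau offset, so the analysis pipeline must recover the
#' configured offsets to machine precision.
#'
#' @param ... Overrides passed on to [sim_params()].
#' @return A `sim_params` object.
#' @export
sim_params_noiseless <- function(...) {
  args <- list(pulse_amp = 0, spike_amp = 0, eyelid_spike_amp = 0,
               noise_sd = 0, drift_sd = 0, rate_jitter = 0)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

#' Cohort specification for the simulator
#'
#' Describes a simulated patient cohort: size, repetitions, which patients
#' perform the eyelid-closure run, and the between-patient dispersion of the
#' generative parameters. Per-patient parameters are drawn as normal
#' deviations around the shared [sim_params()], with child seeds derived
#' deterministically from the master seed so that per-patient streams are
#' independent and reproducible.
#'
#' @param n_patients Number of patients (default 11).
#' @param n_repetitions Repetitions of each eccentricity block (default 3).
#' @param eyelid_n Number of patients (taken from the start of the cohort)
#'   who also perform the eyelid run (default 9).
#' @param baseline_sd Between-patient SD of baseline IOP (mm Hg,
#'   default 4.5).
#' @param delta_sd Between-patient SD of each plateau offset: a scalar or a
#'   matrix shaped like the offset table (default
#'   [default_offset_dispersion()]).
#' @param eyelid_sd Between-patient SD of the eyelid-closure offset
#'   (default 1.0).
#' @param eccentricities Eccentricity blocks simulated (default
#'   `c(10, 20, 25)`).
#' @param seed Master seed (integer).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 11, n_repetitions = 3, eyelid_n = 9,
                        baseline_sd = 4.5,
                        delta_sd = default_offset_dispersion(),
                        eyelid_sd = 1.0,
                        eccentricities = c(10, 20, 25), seed = 1) {
  if (n_patients < 1L) stop("n_patients must be >= 1")
  if (baseline_sd < 0 || eyelid_sd < 0 || any(delta_sd < 0))
    stop("dispersion parameters must be >= 0")
  if (eyelid_n > n_patients) stop("eyelid_n cannot exceed n_patients")
  structure(list(
    n_patients = as.integer(n_patients),
    n_repetitions = as.integer(n_repetitions),
    eyelid_n = as.integer(eyelid_n),
    baseline_sd = baseline_sd, delta_sd = delta_sd, eyelid_sd = eyelid_sd,
    eccentricities = eccentricities, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Derive a reproducible child seed from a master seed
#'
#' Linear-congruential mixing of (master seed, stream index); keeps results
#' below 2^31 so they remain valid R integer seeds.
#'
#' @param master Master seed (integer).
#' @param index Stream index (integer >= 0).
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483563
  x <- (abs(as.numeric(master)) %% m)
  x <- (x * 40014 + as.numeric(index) * 40692 + 12211) %% m
  x <- (x * 40014 + 2531011) %% m
  as.integer(x)
}

.epoch_delta <- function(params, label, eccentricity) {
  out <- numeric(length(label))
  gz <- label %in% GAZE_LABELS
  if (any(gz)) {
    cols <- match(as.character(eccentricity[gz]), colnames(params$offset_table))
    if (anyNA(cols))
      stop("offset_table has no column for eccentricity ",
           paste(unique(eccentricity[gz][is.na(cols)]), collapse = ", "))
    out[gz] <- params$offset_table[cbind(match(label[gz], rownames(params$offset_table)), cols)]
  }
  out[label == "CLOSED"] <- params$eyelid_offset
  out
}

#' Simulate one telemetry trace for a schedule
#'
#' Samples the generative model described in [sim_params()] on a uniform
#' 1/rate grid (plus optional timestamp jitter) spanning the schedule, and
#' returns the trace together with a ground-truth event table listing each
#' epoch's true plateau offset and the signed transient fired at its onset.
#' Deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param schedule An [epoch_schedule()].
#' @param seed Integer seed.
#' @param patient_id Patient id for the trace (defaults to the schedule's).
#' @return A list with elements `trace` ([iop_trace()]) and `truth`
#'   (data frame: `ordinal`, `label`, `eccentricity_deg`, `repetition`,
#'   `start_s`, `end_s`, `delta_true`, `spike`).
#' @export
simulate_trace <- function(params, schedule, seed = 1,
                           patient_id = schedule$patient_id) {
  stopifnot(inherits(params, "sim_params"))
  validate_schedule(schedule)
  ep <- schedule$epochs
  delta <- .epoch_delta(params, ep$label, ep$eccentricity_deg)
  tau <- ifelse(ep$label == "CLOSED", params$eyelid_tau, params$spike_tau)
  # transient signed toward the new plateau; always positive for closure
  jump <- delta - c(0, delta[-length(delta)])
  amp <- ifelse(ep$label == "CLOSED", params$eyelid_spike_amp,
                params$spike_amp * sign(jump))

  t_end <- max(ep$end_s)
  k <- 0:(ceiling(t_end * params$rate) + 1L)
  set.seed(seed)
  if (params$rate_jitter > 0) {
    tt <- (k + stats::runif(length(k), -params$rate_jitter,
                            params$rate_jitter)) / params$rate
  } else tt <- k / params$rate
  keep <- tt >= ep$start_s[1L] & tt < t_end
  tt <- tt[keep]
  n <- length(tt)
  ei <- findInterval(tt, ep$start_s)
  drift <- if (params$drift_sd > 0) cumsum(stats::rnorm(n, 0, params$drift_sd)) else numeric(n)
  noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else numeric(n)
  pulse <- if (params$pulse_amp > 0)
    (params$pulse_amp / 2) * sin(2 * pi * params$heart_rate * tt) else numeric(n)
  spike <- amp[ei] * exp(-(tt - ep$start_s[ei]) / tau[ei])
  iop <- params$baseline_iop + delta[ei] + spike + pulse + drift + noise
  list(
    trace = iop_trace(tt, iop, patient_id = patient_id,
                      nominal_rate = params$rate),
    truth = data.frame(ordinal = ep$ordinal, label = ep$label,
                       eccentricity_deg = ep$eccentricity_deg,
                       repetition = ep$repetition,
                       start_s = ep$start_s, end_s = ep$end_s,
                       delta_true = delta, spike = amp,
                       stringsAsFactors = FALSE))
}

#' Inject dropout and cough artifacts into a trace
#'
#' Samples inside dropout spans are removed (antenna misalignment);
#' overlapping spans are merged with a warning. A cough is modelled as a
#' short (default 0.5 s) high-amplitude positive boxcar transient added at
#' each given time.
#'
#' @param trace An [iop_trace()].
#' @param dropout_spans Data frame or 2-column matrix of `(start_s, end_s)`
#'   spans to blank out, or `NULL`.
#' @param cough_times Numeric vector of cough onset times (s), or `NULL`.
#' @param cough_amp Cough transient amplitude (mm Hg, default 10).
#' @param cough_duration Cough transient duration (s, default 0.5).
#' @param seed Unused; accepted for call-signature stability (the artifact
#'   model is deterministic).
#' @return The modified [iop_trace()].
#' @export
inject_artifacts <- function(trace, dropout_spans = NULL, cough_times = NULL,
                             cough_amp = 10, cough_duration = 0.5,
                             seed = NULL) {
  stopifnot(inherits(trace, "iop_trace"))
  tt <- trace$time_s; pr <- trace$iop
  if (!is.null(dropout_spans) && NROW(dropout_spans)) {
    sp <- as.data.frame(dropout_spans)
    names(sp)[1:2] <- c("start_s", "end_s")
    if (any(sp$end_s <= sp$start_s)) stop("dropout spans must have end > start")
    if (any(sp$start_s < min(tt) - 1e-9) || any(sp$end_s > max(tt) + 1e-9))
      stop("dropout spans must lie within the trace duration")
    sp <- sp[order(sp$start_s), , drop = FALSE]
    merged <- sp[1L, , drop = FALSE]
    overlap <- FALSE
    if (nrow(sp) > 1L) for (i in 2:nrow(sp)) {
      j <- nrow(merged)
      if (sp$start_s[i] < merged$end_s[j]) {
        merged$end_s[j] <- max(merged$end_s[j], sp$end_s[i]); overlap <- TRUE
      } else merged <- rbind(merged, sp[i, ])
    }
    if (overlap) warning("overlapping dropout spans merged")
    drop <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(merged)))
      drop <- drop | (tt >= merged$start_s[i] & tt < merged$end_s[i])
    tt <- tt[!drop]; pr <- pr[!drop]
  }
  for (tc in cough_times %||% numeric(0)) {
    sel <- tt >= tc & tt < tc + cough_duration
    pr[sel] <- pr[sel] + cough_amp
  }
  iop_trace(tt, pr, patient_id = trace$patient_id,
            nominal_rate = trace$nominal_rate)
}

#' Draw per-patient generative parameters
#'
#' Per-patient baseline, gaze-offset table and eyelid offset are drawn as
#' independent normal deviations around the shared parameters, with the
#' dispersions given in the [cohort_spec()]. Deterministic given the spec's
#' master seed and patient index.
#'
#' @param spec A [cohort_spec()].
#' @param params Shared [sim_params()].
#' @param patient_index Patient index (1-based).
#' @return A `sim_params` object with patient-specific values.
#' @export
draw_patient_params <- function(spec, params, patient_index) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(params, "sim_params"))
  set.seed(derive_seed(spec$seed, 2L * patient_index))
  ot <- params$offset_table
  sdm <- spec$delta_sd
  if (length(sdm) == 1L) sdm <- array(sdm, dim(ot))
  sdm <- as.matrix(sdm)
  dev <- matrix(stats::rnorm(length(ot), 0, as.numeric(sdm)),
                nrow = nrow(ot), dimnames = dimnames(ot))
  p <- params
  p$baseline_iop <- params$baseline_iop + stats::rnorm(1, 0, spec$baseline_sd)
  p$offset_table <- ot + dev
  p$eyelid_offset <- params$eyelid_offset + stats::rnorm(1, 0, spec$eyelid_sd)
  p
}

#' Simulate a patient cohort with known ground truth
#'
#' Builds each patient's protocol via [build_protocol()] (the first
#' `eyelid_n` patients also perform the eyelid run), draws patient-specific
#' parameters via [draw_patient_params()], and simulates each trace with a
#' child seed derived from the master seed. Identical master seeds yield
#' bit-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param params Shared [sim_params()] (defaults to `sim_params()`).
#' @return A list of class `iop_cohort`; each element is a list with
#'   `patient_id`, `trace`, `schedule`, `truth` and `params` (the
#'   patient-level parameter draw).
#' @export
simulate_cohort <- function(spec = cohort_spec(), params = sim_params()) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", i)
    pp <- draw_patient_params(spec, params, i)
    sch <- build_protocol(eccentricities = spec$eccentricities,
                          n_repetitions = spec$n_repetitions,
                          eyelid = i <= spec$eyelid_n, patient_id = pid)
    st <- simulate_trace(pp, sch, seed = derive_seed(spec$seed, 2L * i + 1L),
                         patient_id = pid)
    out[[i]] <- list(patient_id = pid, trace = st$trace, schedule = sch,
                     truth = st$truth, params = pp)
  }
  structure(out, class = "iop_cohort", spec = spec, shared_params = params)
}

#' @export
print.iop_cohort <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("<iop_cohort> %d patients (%d with eyelid run), %d repetition(s), seed %d\n",
              length(x), sp$eyelid_n, sp$n_repetitions, sp$seed))
  invisible(x)
}
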