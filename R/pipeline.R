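#' Configuration of a full pipeline run
#'
#' Bundles everything a reproducible end-to-end run needs: the input mode
#' (simulate a cohort, or read trace/schedule files from directories),
#' generator settings, QC options, analysis toggles, output directory and
#' the master seed.
#'
#' @param mode `"simulate"` or `"from-files"`.
#' @param params [sim_params()] used in simulate mode.
#' @param cohort [cohort_spec()] used in simulate mode (its seed is
#'   overridden by `seed`).
#' @param traces_dir,schedules_dir Directories of `*.csv` trace and schedule
#'   files (from-files mode); files are matched by shared base name.
#' @param out_dir Output directory for tidy CSV tables and the JSON
#'   manifest, or `NULL` to skip writing.
#' @param seed Master seed for all randomness.
#' @param trim_s Epoch trim in seconds (default 2).
#' @param min_fraction QC threshold on retained samples (default 0.5).
#' @param drop_repetition Exclude whole repetitions containing a failing
#'   window (default `FALSE`).
#' @param artifact_spans Optional flagged artifact spans (data frame with
#'   `patient_id`, `start_s`, `end_s`).
#' @param analyses Named logical vector toggling the optional analyses:
#'   `time_course`, `eyelid`, `individual`, `control`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "from-files"),
                       params = sim_params(), cohort = cohort_spec(),
                       traces_dir = NULL, schedules_dir = NULL,
                       out_dir = NULL, seed = 1, trim_s = 2,
                       min_fraction = 0.5, drop_repetition = FALSE,
                       artifact_spans = NULL,
                       analyses = c(time_course = TRUE, eyelid = TRUE,
                                    individual = TRUE, control = TRUE)) {
  mode <- match.arg(mode)
  if (mode == "from-files" && (is.null(traces_dir) || is.null(schedules_dir)))
    stop("from-files mode needs traces_dir and schedules_dir")
  cohort$seed <- as.integer(seed)
  structure(list(mode = mode, params = params, cohort = cohort,
                 traces_dir = traces_dir, schedules_dir = schedules_dir,
                 out_dir = out_dir, seed = as.integer(seed), trim_s = trim_s,
                 min_fraction = min_fraction,
                 drop_repetition = drop_repetition,
                 artifact_spans = artifact_spans, analyses = analyses),
            class = "run_config")
}

#' Analyse a cohort of traces and schedules
#'
#' The core fitting routine: segments every patient's trace into trimmed
#' epoch windows, applies quality control, computes baseline-referenced
#' responses, and runs the full inferential battery — condition-level group
#' summary, three-way within-subject RM-ANOVA with Greenhouse-Geisser
#' correction, Holm-corrected per-direction post-hoc t-tests, within-epoch
#' time-course statistics and their correlation, vertical composites with
#' Holm-corrected one-sample tests, the per-patient extreme-direction
#' contrast, the internal-control test, and the eyelid-vs-downgaze
#' comparison (when closure epochs are present).
#'
#' @param traces List of [iop_trace()] objects (or a single trace).
#' @param schedules List of matching [epoch_schedule()] objects.
#' @param trim_s,min_fraction,drop_repetition,artifact_spans,analyses See
#'   [run_config()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class `iop_gaze_fit`; see [summary.iop_gaze_fit()].
#' @export
analyze_cohort <- function(traces, schedules, trim_s = 2, min_fraction = 0.5,
                           drop_repetition = FALSE, artifact_spans = NULL,
                           analyses = c(time_course = TRUE, eyelid = TRUE,
                                        individual = TRUE, control = TRUE),
                           alpha = 0.05) {
  if (inherits(traces, "iop_trace")) traces <- list(traces)
  if (inherits(schedules, "epoch_schedule")) schedules <- list(schedules)
  stopifnot(length(traces) == length(schedules))
  an <- function(nm) { v <- unname(analyses[nm]); is.na(v) || isTRUE(v) }
  windows <- NULL
  for (i in seq_along(traces)) {
    w <- extract_windows(traces[[i]], schedules[[i]], trim_s = trim_s)
    windows <- rbind(windows, w)
  }
  windows <- qc_filter(windows, min_fraction = min_fraction,
                       artifact_spans = artifact_spans,
                       drop_repetition = drop_repetition)
  log_stage <- function(...) message(sprintf(...))
  log_stage("segment: %d windows from %d patient(s); %d fail QC",
            nrow(windows), length(traces), sum(!windows$qc_pass))

  records <- compute_delta_iop(windows)
  tw <- compute_time_windows(windows)
  group <- aggregate_group(records)

  # cell table for the ANOVA: one response per patient x direction x
  # eccentricity x repetition (control epochs excluded)
  cell <- records[records$qc_pass & !records$is_control, ]
  anova_tab <- tryCatch(
    rm_anova_within(cell, dv = "delta_iop", subject = "patient_id",
                    within = c("direction", "eccentricity_deg", "repetition")),
    error = function(e) { log_stage("anova skipped: %s", conditionMessage(e)); NULL })

  # post-hoc: per eccentricity, eight one-sample t-tests on the per-patient
  # responses, Holm-corrected within the eccentricity family
  posthoc <- NULL
  pp <- aggregate(delta_iop ~ patient_id + direction + eccentricity_deg,
                  cell, mean)
  for (e in sort(unique(pp$eccentricity_deg))) {
    rows <- NULL
    for (d in GAZE_LABELS) {
      v <- pp$delta_iop[pp$eccentricity_deg == e & pp$direction == d]
      if (length(v) < 2L) next
      tt <- one_sample_t(v)
      rows <- rbind(rows, data.frame(
        eccentricity_deg = e, direction = d, n = tt$n,
        estimate = tt$estimate, sem = tt$sem, statistic = tt$statistic,
        df = tt$df, p = tt$p, stringsAsFactors = FALSE))
    }
    if (is.null(rows)) next
    h <- holm_adjust(rows$p, alpha = alpha)
    rows$holm_threshold <- h$threshold
    rows$holm_threshold_rounded <- h$threshold_rounded
    rows$reject <- h$reject
    rows$p_holm <- h$p_adj
    posthoc <- rbind(posthoc, rows)
  }

  # time-course summary and TW_initial vs dDeltaIOP correlation across the
  # per-condition group means
  tw_summary <- NULL; tw_corr <- NULL
  if (an("time_course")) {
    twc <- tw[tw$qc_pass & !tw$is_control & tw$tw_valid, ]
    if (nrow(twc)) {
      ppc <- aggregate(cbind(tw_initial, tw_final, d_delta_iop) ~
                         patient_id + direction + eccentricity_deg, twc, mean)
      tw_summary <- aggregate(cbind(tw_initial, tw_final, d_delta_iop) ~
                                direction + eccentricity_deg, ppc, mean)
      if (nrow(tw_summary) >= 3L)
        tw_corr <- linear_corr(tw_summary$tw_initial, tw_summary$d_delta_iop)
    }
  }

  # eyelid analyses on the closure subset, all on last-2-s values
  eyelid <- NULL; eyelid_means <- NULL; composites <- NULL
  composite_tests <- NULL; eyelid_test <- NULL
  if (an("eyelid") && any(windows$label == "CLOSED")) {
    eyelid <- compute_eyelid_deltas(windows)
    eyelid_means <- eyelid_patient_means(eyelid)
    composites <- vertical_composites(tw, value = "tw_final")
    sub <- composites[composites$patient_id %in% eyelid_means$patient_id, ]
    # one-sample tests of each composite and the eyelid response vs 0,
    # Holm-corrected as one family (3 SNT + 3 INT + eyelid)
    fam <- NULL
    for (e in sort(unique(sub$eccentricity_deg), decreasing = TRUE))
      for (side in c("snt", "int")) {
        v <- sub[[side]][sub$eccentricity_deg == e & sub$complete]
        if (length(v) < 2L) next
        tt <- one_sample_t(v)
        fam <- rbind(fam, data.frame(
          condition = sprintf("%g%s", e, toupper(side)), n = tt$n,
          estimate = tt$estimate, sem = tt$sem, statistic = tt$statistic,
          df = tt$df, p = tt$p, stringsAsFactors = FALSE))
      }
    if (nrow(eyelid_means) >= 2L) {
      tt <- one_sample_t(eyelid_means$delta_iop)
      fam <- rbind(fam, data.frame(
        condition = "eyelid", n = tt$n, estimate = tt$estimate, sem = tt$sem,
        statistic = tt$statistic, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE))
    }
    if (!is.null(fam)) {
      h <- holm_adjust(fam$p, alpha = alpha)
      fam$holm_threshold <- h$threshold
      fam$holm_threshold_rounded <- h$threshold_rounded
      fam$reject <- h$reject
      composite_tests <- fam
    }
    if (nrow(eyelid_means) >= 2L)
      eyelid_test <- eyelid_vs_downgaze(eyelid_means, composites = sub,
                                        eccentricity = 25)
  } else if (an("eyelid")) {
    log_stage("eyelid analysis skipped: no CLOSED epochs in any schedule")
  }

  individual <- NULL
  if (an("individual"))
    individual <- individual_extreme_contrast(records, alpha = alpha)
  control <- NULL
  if (an("control") && any(records$is_control))
    control <- internal_control_test(records)
  else if (an("control"))
    log_stage("internal-control test skipped: no control epochs found")

  normality <- if (nrow(pp) >= 3L && nrow(pp) <= 5000L)
    normality_screen(pp$delta_iop) else NULL

  structure(list(
    windows = windows, records = records, time_windows = tw,
    group_summary = group, anova = anova_tab, posthoc = posthoc,
    tw_summary = tw_summary, tw_correlation = tw_corr,
    eyelid = eyelid, eyelid_means = eyelid_means,
    composites = composites, composite_tests = composite_tests,
    eyelid_test = eyelid_test, individual = individual, control = control,
    normality = normality,
    n_patients = length(traces), alpha = alpha, call = match.call()),
    class = "iop_gaze_fit")
}

#' Run the full pipeline from a configuration
#'
#' Simulates (or reads) the cohort, analyses it with [analyze_cohort()],
#' and, if an output directory is configured, writes the tidy CSV tables and
#' a JSON manifest recording seed and configuration hash. Deterministic
#' given the seed.
#'
#' @param config A [run_config()].
#' @return An `iop_gaze_fit` with the `config` attached; in simulate mode
#'   also the cohort ground truth (`$truth`) and a per-condition recovery
#'   table (`$recovery`) comparing estimated against configured offsets.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$cohort, config$params)
    traces <- lapply(cohort, `[[`, "trace")
    schedules <- lapply(cohort, `[[`, "schedule")
    truth <- do.call(rbind, lapply(cohort, function(p)
      cbind(patient_id = p$patient_id, p$truth)))
  } else {
    tf <- sort(list.files(config$traces_dir, "\\.csv$", full.names = TRUE))
    sf <- sort(list.files(config$schedules_dir, "\\.csv$", full.names = TRUE))
    if (!length(tf)) stop("no trace files in ", config$traces_dir)
    if (length(tf) != length(sf))
      stop("trace and schedule directories list different file counts")
    traces <- lapply(tf, read_iop_trace)
    schedules <- lapply(sf, read_schedule)
    truth <- NULL
  }
  fit <- analyze_cohort(traces, schedules, trim_s = config$trim_s,
                        min_fraction = config$min_fraction,
                        drop_repetition = config$drop_repetition,
                        artifact_spans = config$artifact_spans,
                        analyses = config$analyses)
  fit$config <- config
  fit$truth <- truth
  if (config$mode == "simulate") {
    ot <- config$params$offset_table
    gs <- fit$group_summary[fit$group_summary$direction != "Overall", ]
    fit$recovery <- data.frame(
      eccentricity_deg = gs$eccentricity_deg, direction = gs$direction,
      delta_true = ot[cbind(gs$direction, as.character(gs$eccentricity_deg))],
      delta_est = gs$delta_mean)
    fit$recovery$error <- fit$recovery$delta_est - fit$recovery$delta_true
  }
  if (!is.null(config$out_dir)) write_results(fit, config$out_dir)
  fit
}

#' Write the tidy result tables and manifest of a fit
#'
#' @param fit An `iop_gaze_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "iop_gaze_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) if (!is.null(x) && NROW(x))
    utils::write.csv(x, file.path(dir, name), row.names = FALSE)
  wcsv(fit$records, "delta_iop.csv")
  wcsv(fit$time_windows, "time_windows.csv")
  wcsv(fit$group_summary, "group_summary.csv")
  wcsv(as.data.frame(fit$anova), "anova.csv")
  wcsv(fit$posthoc, "posthoc.csv")
  wcsv(fit$tw_summary, "tw_summary.csv")
  wcsv(fit$eyelid, "eyelid.csv")
  wcsv(fit$composites, "composites.csv")
  wcsv(fit$composite_tests, "composite_tests.csv")
  wcsv(fit$individual, "individual.csv")
  wcsv(fit$control, "control.csv")
  if (!is.null(fit$eyelid_test))
    wcsv(data.frame(estimate = fit$eyelid_test$estimate,
                    sem = fit$eyelid_test$sem,
                    statistic = fit$eyelid_test$statistic,
                    df = fit$eyelid_test$df, p = fit$eyelid_test$p,
                    n = fit$eyelid_test$n), "eyelid_test.csv")
  if (!is.null(fit$recovery)) wcsv(fit$recovery, "recovery.csv")
  cfg <- fit$config
  manifest <- list(
    package = "iopgaze",
    version = as.character(utils::packageVersion("iopgaze")),
    seed = if (!is.null(cfg)) cfg$seed else NA,
    mode = if (!is.null(cfg)) cfg$mode else "direct",
    n_patients = fit$n_patients,
    config_hash = if (!is.null(cfg)) {
      # hash the scientific configuration only, not run-local paths
      cfg$out_dir <- cfg$traces_dir <- cfg$schedules_dir <- NULL
      .stable_hash(cfg)
    } else NA,
    tables = list.files(dir, "\\.csv$"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

# FNV-1a hash of the deparsed object; stable across runs of the same build.
.stable_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 2166136261
  for (v in b) h <- (bitwXor(as.integer(h %% 2^31), v) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Parameter-recovery and calibration harness
#'
#' Repeats simulate-and-analyse `n_replicates` times and reports, per gaze
#' condition, the bias and RMSE of the estimated group-level response
#' against the configured plateau offset, together with the rejection rate
#' of the Greenhouse-Geisser-corrected direction effect (the empirical
#' type-I error when the configured offsets are all equal).
#'
#' @param config A [run_config()] in simulate mode.
#' @param n_replicates Number of replicate cohorts (`>= 2`).
#' @param keep_anova Record the direction-effect p-value of each replicate
#'   (default `TRUE`).
#' @return An object of class `recovery_report`: list with the per-condition
#'   data frame `conditions` (`delta_true`, `mean_est`, `bias`, `rmse`),
#'   `p_direction` (vector, if `keep_anova`), `rejection_rate`, and
#'   `n_replicates`.
#' @export
validate_recovery <- function(config, n_replicates, keep_anova = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "simulate") stop("validate_recovery needs simulate mode")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  ot <- config$params$offset_table
  errs <- NULL
  pdir <- numeric(0)
  analyses <- c(time_course = FALSE, eyelid = FALSE, individual = FALSE,
                control = FALSE)
  for (r in seq_len(n_replicates)) {
    spec <- config$cohort
    spec$seed <- derive_seed(config$seed, r)
    cohort <- simulate_cohort(spec, config$params)
    windows <- NULL
    for (p in cohort)
      windows <- rbind(windows, extract_windows(p$trace, p$schedule,
                                                trim_s = config$trim_s))
    windows <- qc_filter(windows, min_fraction = config$min_fraction)
    records <- compute_delta_iop(windows)
    cell <- records[records$qc_pass & !records$is_control, ]
    est <- aggregate(delta_iop ~ direction + eccentricity_deg,
                     aggregate(delta_iop ~ patient_id + direction +
                                 eccentricity_deg, cell, mean), mean)
    est$delta_true <- ot[cbind(est$direction,
                               as.character(est$eccentricity_deg))]
    est$error <- est$delta_iop - est$delta_true
    est$replicate <- r
    errs <- rbind(errs, est)
    if (keep_anova) {
      a <- rm_anova_within(cell)
      pdir <- c(pdir, a$p_gg[a$effect == "direction"])
    }
  }
  cond <- aggregate(error ~ direction + eccentricity_deg, errs, function(e)
    c(bias = mean(e), rmse = sqrt(mean(e^2))))
  cond <- cbind(cond[, 1:2], cond$error)
  cond$delta_true <- ot[cbind(cond$direction,
                              as.character(cond$eccentricity_deg))]
  structure(list(conditions = cond,
                 p_direction = if (keep_anova) pdir else NULL,
                 rejection_rate = if (keep_anova) mean(pdir < 0.05) else NA,
                 n_replicates = n_replicates,
                 errors = errs),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates: max |bias| %.3f, max RMSE %.3f mm Hg",
              x$n_replicates, max(abs(x$conditions$bias)),
              max(x$conditions$rmse)))
  if (!is.null(x$p_direction))
    cat(sprintf("; GG direction-effect rejection rate %.3f",
                x$rejection_rate))
  cat("\n")
  invisible(x)
}
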