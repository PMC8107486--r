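#' Extract trimmed analysis windows for every epoch
#'
#' For each epoch the first and last `trim_s` seconds are excluded, so the
#' analysis window is the half-open interval
#' `[start_s + trim_s, end_s - trim_s)`; for the standard 12-s gaze epoch
#' with the default 2-s trim this is the 8-s analysis interval. The trim
#' avoids IOP transients during the eye movements that bracket each epoch.
#' Alongside the window mean, the first and last 2 s of the analysis
#' interval (the initial and final time windows used by the time-course
#' statistics) and the untrimmed last 2 s of the epoch (used for
#' eyelid-closure analysis) are summarised.
#'
#' @param trace An [iop_trace()].
#' @param schedule An [epoch_schedule()] for the same session.
#' @param trim_s Seconds trimmed from each end of every epoch (default 2).
#' @return A data frame with one row per epoch: epoch descriptors, window
#'   bounds, expected and observed sample counts, `mean_iop`, sub-window
#'   means `tw_initial_mean`/`tw_final_mean`/`last2_mean` with their counts,
#'   and a `valid` flag (window contains at least one sample).
#' @export
extract_windows <- function(trace, schedule, trim_s = 2) {
  stopifnot(inherits(trace, "iop_trace"), inherits(schedule, "epoch_schedule"))
  ep <- schedule$epochs
  dur <- ep$end_s - ep$start_s
  short <- which(dur <= 2 * trim_s)
  if (length(short))
    stop(sprintf("epoch %d (%s, %.0f s) is shorter than twice the trim of %g s",
                 ep$ordinal[short[1L]], ep$label[short[1L]], dur[short[1L]],
                 trim_s))
  tt <- trace$time_s
  csum <- c(0, cumsum(trace$iop))
  wmean <- function(from, to) {
    lo <- findInterval(from, tt, left.open = TRUE)
    hi <- findInterval(to, tt, left.open = TRUE)
    n <- hi - lo
    m <- ifelse(n > 0, (csum[hi + 1L] - csum[lo + 1L]) / pmax(n, 1L), NA_real_)
    list(n = n, mean = m)
  }
  ws <- ep$start_s + trim_s
  we <- ep$end_s - trim_s
  main <- wmean(ws, we)
  has_tw <- (we - ws) >= 4
  twi <- wmean(ws, ws + 2)
  twf <- wmean(we - 2, we)
  twi$n[!has_tw] <- 0L; twi$mean[!has_tw] <- NA_real_
  twf$n[!has_tw] <- 0L; twf$mean[!has_tw] <- NA_real_
  last2 <- wmean(ep$end_s - 2, ep$end_s)
  data.frame(
    patient_id = trace$patient_id,
    ordinal = ep$ordinal, label = ep$label,
    eccentricity_deg = ep$eccentricity_deg, repetition = ep$repetition,
    start_s = ep$start_s, end_s = ep$end_s,
    win_start_s = ws, win_end_s = we,
    n_expected = as.integer(floor((we - ws) * trace$nominal_rate + 1e-9)),
    n_obs = main$n, mean_iop = main$mean,
    tw_initial_mean = twi$mean, tw_initial_n = twi$n,
    tw_final_mean = twf$mean, tw_final_n = twf$n,
    last2_mean = last2$mean, last2_n = last2$n,
    valid = main$n >= 1L,
    stringsAsFactors = FALSE)
}

#' Flag windows that fail quality control
#'
#' A window fails when it retains fewer than `min_fraction` of its expected
#' samples (dropout) or overlaps a declared artifact span (e.g. a cough).
#' With `drop_repetition = TRUE`, any failing window causes the entire
#' eccentricity x repetition block it belongs to to be excluded, mirroring
#' exclusion of whole repetitions rather than single epochs.
#'
#' @param windows Data frame from [extract_windows()].
#' @param min_fraction Minimum retained fraction of expected samples
#'   (default 0.5).
#' @param artifact_spans Optional data frame of flagged spans with columns
#'   `start_s`, `end_s` and optionally `patient_id`.
#' @param drop_repetition Drop whole blocks containing a failing window
#'   (default `FALSE`).
#' @return `windows` with a logical `qc_pass` column added.
#' @export
qc_filter <- function(windows, min_fraction = 0.5, artifact_spans = NULL,
                      drop_repetition = FALSE) {
  w <- windows
  pass <- w$valid & (w$n_obs / pmax(w$n_expected, 1L)) >= min_fraction
  if (!is.null(artifact_spans) && NROW(artifact_spans)) {
    sp <- as.data.frame(artifact_spans)
    for (i in seq_len(nrow(sp))) {
      hit <- w$win_start_s < sp$end_s[i] & w$win_end_s > sp$start_s[i]
      if ("patient_id" %in% names(sp))
        hit <- hit & w$patient_id == sp$patient_id[i]
      pass <- pass & !hit
    }
  }
  if (drop_repetition) {
    # baselines belong to the block of the gaze/CLOSED epoch they precede
    block_ecc <- w$eccentricity_deg
    for (pid in unique(w$patient_id)) {
      i <- which(w$patient_id == pid)
      i <- i[order(w$ordinal[i])]
      v <- ifelse(w$label[i] == "PRIMARY", NA, w$eccentricity_deg[i])
      for (j in rev(seq_along(v))[-1]) if (is.na(v[j])) v[j] <- v[j + 1L]
      for (j in seq_along(v)[-1]) if (is.na(v[j])) v[j] <- v[j - 1L]
      block_ecc[i] <- v
    }
    key <- interaction(w$patient_id, block_ecc, w$repetition, drop = TRUE)
    bad <- tapply(!pass, key, any)
    pass <- pass & !bad[key]
  }
  w$qc_pass <- as.logical(pass)
  w
}

.ensure_qc <- function(windows) {
  if (is.null(windows$qc_pass)) windows$qc_pass <- windows$valid
  windows
}

# Pair every non-PRIMARY window with its immediately preceding PRIMARY
# baseline window (by schedule order). Errors if a baseline is absent.
.pair_baseline <- function(windows, labels) {
  w <- windows[order(windows$patient_id, windows$ordinal), , drop = FALSE]
  out <- NULL
  for (pid in unique(w$patient_id)) {
    wp <- w[w$patient_id == pid, , drop = FALSE]
    idx <- which(wp$label %in% labels)
    if (!length(idx)) next
    prev <- match(wp$ordinal[idx] - 1L, wp$ordinal)
    if (anyNA(prev) || any(wp$label[prev] != "PRIMARY"))
      stop("epoch ", wp$ordinal[idx[which(is.na(prev) | wp$label[prev] != "PRIMARY")[1L]]],
           " of patient ", pid, " has no immediately preceding PRIMARY baseline")
    pair <- wp[idx, , drop = FALSE]
    pair$baseline_mean <- wp$mean_iop[prev]
    pair$baseline_n <- wp$n_obs[prev]
    pair$baseline_qc <- wp$qc_pass[prev]
    out <- rbind(out, pair)
  }
  out
}

# Mark the closing internal-control superior gaze: within an eccentricity x
# repetition block, a second S epoch (after the full clockwise round) is the
# control repeat.
.flag_control <- function(records) {
  records$is_control <- FALSE
  key <- interaction(records$patient_id, records$eccentricity_deg,
                     records$repetition, drop = TRUE)
  for (k in levels(key)) {
    i <- which(key == k & records$direction == "S")
    if (length(i) > 1L) records$is_control[i[order(records$ordinal[i])][-1L]] <- TRUE
  }
  records
}

#' Baseline-referenced IOP responses per gaze epoch
#'
#' For every quality-controlled gaze epoch, the IOP response is
#' `delta_iop = gaze_mean - baseline_mean`, where the baseline is the mean
#' of the immediately preceding PRIMARY window. Positive values denote an
#' IOP increase relative to primary gaze. The closing internal-control
#' superior epoch of each block is flagged `is_control` and is excluded from
#' condition-level aggregation (it feeds [internal_control_test()]).
#'
#' @param windows Data frame from [extract_windows()] (after [qc_filter()];
#'   if `qc_pass` is absent, sample presence is used).
#' @return A data frame with one row per gaze epoch: `patient_id`,
#'   `direction`, `eccentricity_deg`, `repetition`, `baseline_mean`,
#'   `gaze_mean`, `delta_iop`, `qc_pass`, `is_control`.
#' @export
compute_delta_iop <- function(windows) {
  w <- .ensure_qc(windows)
  pair <- .pair_baseline(w, GAZE_LABELS)
  if (is.null(pair)) return(.empty_delta())
  rec <- data.frame(
    patient_id = pair$patient_id, direction = pair$label,
    eccentricity_deg = pair$eccentricity_deg, repetition = pair$repetition,
    ordinal = pair$ordinal,
    baseline_mean = pair$baseline_mean, gaze_mean = pair$mean_iop,
    delta_iop = pair$mean_iop - pair$baseline_mean,
    qc_pass = pair$qc_pass & pair$baseline_qc,
    stringsAsFactors = FALSE)
  .flag_control(rec)
}

.empty_delta <- function() {
  data.frame(patient_id = character(0), direction = character(0),
             eccentricity_deg = numeric(0), repetition = numeric(0),
             ordinal = integer(0), baseline_mean = numeric(0),
             gaze_mean = numeric(0), delta_iop = numeric(0),
             qc_pass = logical(0), is_control = logical(0))
}

#' Within-epoch time-course statistics (initial vs final time window)
#'
#' For each gaze epoch, the initial and final 2 s of the analysis interval
#' are summarised as baseline-referenced responses (`tw_initial`,
#' `tw_final`, both relative to the same preceding PRIMARY baseline), and
#' their difference `d_delta_iop = tw_initial - tw_final`. A positive
#' `d_delta_iop` means the response declined while the gaze was held.
#'
#' @param windows Data frame from [extract_windows()].
#' @return A data frame like [compute_delta_iop()] with added columns
#'   `tw_initial`, `tw_final`, `d_delta_iop` and a `tw_valid` flag (both
#'   sub-windows non-empty).
#' @export
compute_time_windows <- function(windows) {
  w <- .ensure_qc(windows)
  pair <- .pair_baseline(w, GAZE_LABELS)
  if (is.null(pair)) {
    out <- .empty_delta()
    out$tw_initial <- out$tw_final <- out$d_delta_iop <- numeric(0)
    out$tw_valid <- logical(0)
    return(out)
  }
  rec <- data.frame(
    patient_id = pair$patient_id, direction = pair$label,
    eccentricity_deg = pair$eccentricity_deg, repetition = pair$repetition,
    ordinal = pair$ordinal,
    baseline_mean = pair$baseline_mean, gaze_mean = pair$mean_iop,
    delta_iop = pair$mean_iop - pair$baseline_mean,
    tw_initial = pair$tw_initial_mean - pair$baseline_mean,
    tw_final = pair$tw_final_mean - pair$baseline_mean,
    d_delta_iop = pair$tw_initial_mean - pair$tw_final_mean,
    tw_valid = pair$tw_initial_n > 0L & pair$tw_final_n > 0L,
    qc_pass = pair$qc_pass & pair$baseline_qc,
    stringsAsFactors = FALSE)
  .flag_control(rec)
}

#' Eyelid-closure IOP responses
#'
#' For each CLOSED epoch, the mean IOP over the last 2 s of the epoch (after
#' the initial closure transient has decayed) minus the mean of the
#' immediately preceding PRIMARY baseline window. The per-patient summary
#' averages over the closure repetitions.
#'
#' @param windows Data frame from [extract_windows()].
#' @return A data frame with one row per closure epoch (`patient_id`,
#'   `repetition`, `baseline_mean`, `closure_mean_last2s`, `delta_iop`,
#'   `qc_pass`); per-patient means are available via
#'   [eyelid_patient_means()]. Empty (with a warning) if no CLOSED epochs
#'   are present.
#' @export
compute_eyelid_deltas <- function(windows) {
  w <- .ensure_qc(windows)
  if (!any(w$label == "CLOSED")) {
    warning("no CLOSED epochs in input; returning empty result")
    return(data.frame(patient_id = character(0), repetition = numeric(0),
                      baseline_mean = numeric(0),
                      closure_mean_last2s = numeric(0),
                      delta_iop = numeric(0), qc_pass = logical(0)))
  }
  pair <- .pair_baseline(w, "CLOSED")
  data.frame(
    patient_id = pair$patient_id, repetition = pair$repetition,
    baseline_mean = pair$baseline_mean,
    closure_mean_last2s = pair$last2_mean,
    delta_iop = pair$last2_mean - pair$baseline_mean,
    qc_pass = pair$qc_pass & pair$baseline_qc & pair$last2_n > 0L,
    stringsAsFactors = FALSE)
}

#' Per-patient mean eyelid-closure response
#'
#' @param eyelid Data frame from [compute_eyelid_deltas()].
#' @return Data frame `patient_id`, `delta_iop` (mean over quality-passing
#'   closure repetitions), `n_repetitions`.
#' @export
eyelid_patient_means <- function(eyelid) {
  e <- eyelid[eyelid$qc_pass, , drop = FALSE]
  if (!nrow(e))
    return(data.frame(patient_id = character(0), delta_iop = numeric(0),
                      n_repetitions = integer(0)))
  agg <- aggregate(delta_iop ~ patient_id, e, mean)
  agg$n_repetitions <- as.integer(table(e$patient_id)[agg$patient_id])
  agg
}

#' Condition-level group summary of IOP responses
#'
#' Repetitions are first averaged within each patient x direction x
#' eccentricity cell (quality-passing, non-control records only); group mean
#' and SEM (SD over patients divided by sqrt(n)) are then computed per
#' condition, for the gaze-position IOP, the preceding baseline IOP and the
#' response delta_iop. An `Overall` row per eccentricity averages the eight
#' per-direction group means; its SEM is taken over the per-patient overall
#' means. With a single patient the SEM is reported as missing.
#'
#' @param records Data frame from [compute_delta_iop()].
#' @return Data frame with columns `eccentricity_deg`, `direction`
#'   (including `"Overall"`), `n`, `position_mean`, `position_sem`,
#'   `baseline_mean`, `baseline_sem`, `delta_mean`, `delta_sem`.
#' @export
aggregate_group <- function(records) {
  r <- records[records$qc_pass & !records$is_control, , drop = FALSE]
  if (!nrow(r)) stop("no quality-passing records to aggregate")
  cell <- aggregate(cbind(gaze_mean, baseline_mean, delta_iop) ~
                      patient_id + direction + eccentricity_deg, r, mean)
  out <- NULL
  for (e in sort(unique(cell$eccentricity_deg))) {
    ce <- cell[cell$eccentricity_deg == e, , drop = FALSE]
    rows <- NULL
    for (d in GAZE_LABELS) {
      cd <- ce[ce$direction == d, , drop = FALSE]
      if (!nrow(cd)) {
        warning(sprintf("condition %s at %g deg has no patients; omitted", d, e))
        next
      }
      n <- nrow(cd)
      sem <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
      rows <- rbind(rows, data.frame(
        eccentricity_deg = e, direction = d, n = n,
        position_mean = mean(cd$gaze_mean), position_sem = sem(cd$gaze_mean),
        baseline_mean = mean(cd$baseline_mean),
        baseline_sem = sem(cd$baseline_mean),
        delta_mean = mean(cd$delta_iop), delta_sem = sem(cd$delta_iop),
        stringsAsFactors = FALSE))
    }
    # Overall row: mean of the per-direction group means; SEM across the
    # per-patient overall means
    pp <- aggregate(cbind(gaze_mean, baseline_mean, delta_iop) ~ patient_id,
                    ce, mean)
    n_pp <- nrow(pp)
    osem <- function(x) if (n_pp > 1L) stats::sd(x) / sqrt(n_pp) else NA_real_
    rows <- rbind(rows, data.frame(
      eccentricity_deg = e, direction = "Overall", n = n_pp,
      position_mean = mean(rows$position_mean),
      position_sem = osem(pp$gaze_mean),
      baseline_mean = mean(rows$baseline_mean),
      baseline_sem = osem(pp$baseline_mean),
      delta_mean = mean(rows$delta_mean), delta_sem = osem(pp$delta_iop),
      stringsAsFactors = FALSE))
    out <- rbind(out, rows)
  }
  out
}
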