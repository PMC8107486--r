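#' Vertical-gaze composites (SNT and INT)
#'
#' Per patient and eccentricity, the upgaze composite `snt` averages the
#' responses for the superonasal, superior and superotemporal directions
#' (SN, S, ST) and the downgaze composite `int` averages the inferotemporal,
#' inferior and inferonasal directions (IT, I, IN). Records are first
#' averaged over repetitions (quality-passing, non-control). A composite
#' whose constituents are not all present is flagged, not silently dropped.
#' When used in the eyelid comparison the input should be last-2-s response
#' values (`value = "tw_final"` on [compute_time_windows()] output).
#'
#' @param records Data frame of response records (from [compute_delta_iop()]
#'   or [compute_time_windows()]).
#' @param value Name of the response column to average (default
#'   `"delta_iop"`).
#' @return Data frame with `patient_id`, `eccentricity_deg`, `snt`, `int`,
#'   `complete` (all six constituents present).
#' @export
vertical_composites <- function(records, value = "delta_iop") {
  r <- records[records$qc_pass & !records$is_control, , drop = FALSE]
  if (!nrow(r)) stop("no quality-passing records")
  r$value <- r[[value]]
  cell <- aggregate(value ~ patient_id + direction + eccentricity_deg, r, mean)
  up <- c("SN", "S", "ST"); down <- c("IT", "I", "IN")
  out <- NULL
  for (pid in unique(cell$patient_id)) for (e in sort(unique(cell$eccentricity_deg))) {
    ce <- cell[cell$patient_id == pid & cell$eccentricity_deg == e, ]
    gv <- function(dirs) {
      v <- ce$value[match(dirs, ce$direction)]
      if (anyNA(v)) NA_real_ else mean(v)
    }
    snt <- gv(up); int <- gv(down)
    out <- rbind(out, data.frame(
      patient_id = pid, eccentricity_deg = e, snt = snt, int = int,
      complete = !is.na(snt) && !is.na(int), stringsAsFactors = FALSE))
  }
  out
}

#' Per-patient contrast of the extreme gaze directions
#'
#' Compares, within each patient, the repetition-matched responses of the
#' direction with the greatest group-level IOP increase against the one with
#' the greatest decrease (by default superior vs inferonasal at 25 degrees)
#' with a paired t-test. Patients with fewer than two matched repetitions
#' are skipped with a flag.
#'
#' @param records Data frame from [compute_delta_iop()].
#' @param dir_hi,dir_lo Directions contrasted (defaults `"S"` vs `"IN"`).
#' @param eccentricity Eccentricity tested (default 25).
#' @param alpha Significance level for the per-patient count (default 0.05).
#' @return Data frame with one row per patient (`patient_id`, `n_pairs`,
#'   `estimate`, `statistic`, `df`, `p`, `significant`, `skipped`);
#'   attribute `n_significant` counts patients with `p < alpha`.
#' @export
individual_extreme_contrast <- function(records, dir_hi = "S", dir_lo = "IN",
                                        eccentricity = 25, alpha = 0.05) {
  r <- records[records$qc_pass & !records$is_control &
                 records$eccentricity_deg == eccentricity, , drop = FALSE]
  out <- NULL
  for (pid in unique(records$patient_id)) {
    hi <- r[r$patient_id == pid & r$direction == dir_hi, ]
    lo <- r[r$patient_id == pid & r$direction == dir_lo, ]
    reps <- intersect(hi$repetition, lo$repetition)
    if (length(reps) < 2L) {
      out <- rbind(out, data.frame(
        patient_id = pid, n_pairs = length(reps), estimate = NA_real_,
        statistic = NA_real_, df = NA_integer_, p = NA_real_,
        significant = NA, skipped = TRUE, stringsAsFactors = FALSE))
      next
    }
    d <- hi$delta_iop[match(reps, hi$repetition)] -
      lo$delta_iop[match(reps, lo$repetition)]
    tt <- paired_t(d)
    out <- rbind(out, data.frame(
      patient_id = pid, n_pairs = length(reps), estimate = tt$estimate,
      statistic = tt$statistic, df = tt$df, p = tt$p,
      significant = tt$p < alpha, skipped = FALSE, stringsAsFactors = FALSE))
  }
  structure(out, n_significant = sum(out$significant, na.rm = TRUE))
}

#' Internal-control test: first vs closing superior gaze
#'
#' Each eccentricity block starts and ends with a superior gaze epoch; a
#' sequential (e.g. tonographic) effect over the session would show up as a
#' systematic difference between them. Per eccentricity, the per-patient
#' mean response of the first superior gaze is compared against the closing
#' control repeat with a paired t-test across patients.
#'
#' @param records Data frame from [compute_delta_iop()] (control epochs must
#'   be present and flagged).
#' @return Data frame with one row per eccentricity (`eccentricity_deg`,
#'   `n`, `estimate`, `sem`, `statistic`, `df`, `p`).
#' @export
internal_control_test <- function(records) {
  if (!any(records$is_control)) stop("no internal-control epochs in records")
  r <- records[records$qc_pass & records$direction == "S", , drop = FALSE]
  out <- NULL
  for (e in sort(unique(r$eccentricity_deg))) {
    re <- r[r$eccentricity_deg == e, ]
    first <- aggregate(delta_iop ~ patient_id, re[!re$is_control, ], mean)
    ctrl <- aggregate(delta_iop ~ patient_id, re[re$is_control, ], mean)
    ids <- intersect(first$patient_id, ctrl$patient_id)
    if (length(ids) < 2L) next
    d <- first$delta_iop[match(ids, first$patient_id)] -
      ctrl$delta_iop[match(ids, ctrl$patient_id)]
    tt <- paired_t(d, label = sprintf("first vs control S at %g deg", e))
    out <- rbind(out, data.frame(
      eccentricity_deg = e, n = tt$n, estimate = tt$estimate, sem = tt$sem,
      statistic = tt$statistic, df = tt$df, p = tt$p,
      stringsAsFactors = FALSE))
  }
  out
}

#' Eyelid closure vs downgaze comparison
#'
#' Patient-matched paired t-test of the eyelid-closure response against the
#' downgaze response at a given eccentricity: either the INT composite (mean
#' of IT, I, IN; the default) or the single inferior direction. Both sides
#' use last-2-s window values for comparability. Patients present in only
#' one input raise an error naming them.
#'
#' @param eyelid Per-patient eyelid means from [eyelid_patient_means()] (or
#'   the per-epoch records from [compute_eyelid_deltas()], which are then
#'   averaged).
#' @param composites Data frame from [vertical_composites()] (required for
#'   `use = "int"`).
#' @param records Time-window records (required for `use = "inferior"`).
#' @param eccentricity Eccentricity of the downgaze comparison (default 25).
#' @param use `"int"` for the composite (default) or `"inferior"` for the
#'   single direction.
#' @return An `iop_ttest` for eyelid minus downgaze, with the matched
#'   per-patient values attached as attribute `data`.
#' @export
eyelid_vs_downgaze <- function(eyelid, composites = NULL, records = NULL,
                               eccentricity = 25,
                               use = c("int", "inferior")) {
  use <- match.arg(use)
  if (!is.null(eyelid$repetition)) eyelid <- eyelid_patient_means(eyelid)
  if (use == "int") {
    if (is.null(composites)) stop("composites are required for use = 'int'")
    dg <- composites[composites$eccentricity_deg == eccentricity &
                       composites$complete, c("patient_id", "int")]
    names(dg)[2L] <- "downgaze"
  } else {
    if (is.null(records)) stop("records are required for use = 'inferior'")
    r <- records[records$qc_pass & !records$is_control &
                   records$direction == "I" &
                   records$eccentricity_deg == eccentricity, ]
    val <- if (!is.null(r$tw_final)) r$tw_final else r$delta_iop
    dg <- aggregate(list(downgaze = val), list(patient_id = r$patient_id),
                    mean)
  }
  unmatched <- c(setdiff(eyelid$patient_id, dg$patient_id),
                 setdiff(dg$patient_id, eyelid$patient_id))
  if (length(unmatched))
    stop("patient subsets differ between eyelid and gaze inputs: ",
         paste(unique(unmatched), collapse = ", "))
  m <- merge(eyelid, dg, by = "patient_id")
  tt <- paired_t(m$delta_iop - m$downgaze,
                 label = sprintf("eyelid closure vs downgaze (%s) at %g deg",
                                 use, eccentricity))
  attr(tt, "data") <- m
  tt
}
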