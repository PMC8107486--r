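#' Build the gaze-protocol epoch schedule
#'
#' Generates the full fixation protocol: for each eccentricity block, an
#' initial PRIMARY baseline, then the eight gaze positions in clockwise order
#' starting superior, each preceded by a PRIMARY baseline, and a closing
#' control pair (a repeat of the superior gaze followed by a final PRIMARY).
#' One block therefore contains 9 gaze-type epochs and 10 PRIMARY epochs.
#' Blocks are repeated `n_repetitions` times per eccentricity. With
#' `eyelid = TRUE`, an eyelid-closure run is appended at the end of the
#' session: a PRIMARY baseline followed by `n_eyelid` pairs of (CLOSED,
#' PRIMARY) epochs.
#'
#' @param eccentricities Gaze eccentricities in degrees, a subset of
#'   `c(10, 20, 25)`.
#' @param gaze_s Duration of each gaze epoch in seconds (default 12).
#' @param baseline_s Duration of each PRIMARY baseline epoch (default 12).
#' @param n_repetitions Number of repetitions of each eccentricity block
#'   (default 3).
#' @param eyelid Append the eyelid-closure run (default `FALSE`).
#' @param eyelid_s Duration of each CLOSED epoch in seconds (default 10).
#' @param n_eyelid Number of closure repetitions (default 4).
#' @param patient_id Patient identifier for the schedule.
#' @return An [epoch_schedule()].
#' @export
#' @examples
#' sch <- build_protocol(25, n_repetitions = 1)
#' table(sch$epochs$label)
build_protocol <- function(eccentricities = c(10, 20, 25), gaze_s = 12,
                           baseline_s = 12, n_repetitions = 3,
                           eyelid = FALSE, eyelid_s = 10, n_eyelid = 4,
                           patient_id = "P01") {
  if (!length(eccentricities) || !all(eccentricities %in% .ECCENTRICITIES))
    stop("eccentricities must be a non-empty subset of {",
         paste(.ECCENTRICITIES, collapse = ", "), "}")
  if (gaze_s <= 4 || baseline_s <= 4 || eyelid_s <= 4)
    stop("epoch durations must exceed 4 s")
  if (n_repetitions < 1L) stop("n_repetitions must be >= 1")

  lab <- character(0); ecc <- numeric(0); dur <- numeric(0); rep_ <- integer(0)
  block_gaze <- c(GAZE_LABELS, "S")        # clockwise + closing control S
  for (e in eccentricities) {
    for (r in seq_len(n_repetitions)) {
      labs <- c(rbind(rep("PRIMARY", length(block_gaze)), block_gaze),
                "PRIMARY")
      lab <- c(lab, labs)
      ecc <- c(ecc, ifelse(labs == "PRIMARY", 0, e))
      dur <- c(dur, ifelse(labs == "PRIMARY", baseline_s, gaze_s))
      rep_ <- c(rep_, rep(r, length(labs)))
    }
  }
  if (eyelid) {
    labs <- c("PRIMARY", rep(c("CLOSED", "PRIMARY"), n_eyelid))
    lab <- c(lab, labs)
    ecc <- c(ecc, rep(0, length(labs)))
    dur <- c(dur, ifelse(labs == "CLOSED", eyelid_s, baseline_s))
    # closure repetition number; the surrounding baselines inherit it
    reps <- c(1L, rep(seq_len(n_eyelid), each = 2L))
    rep_ <- c(rep_, reps)
  }
  end_s <- cumsum(dur)
  epoch_schedule(
    data.frame(label = lab, eccentricity_deg = ecc,
               start_s = end_s - dur, end_s = end_s, repetition = rep_,
               stringsAsFactors = FALSE),
    patient_id = patient_id,
    metadata = sprintf("generated protocol: ecc=%s, reps=%d%s",
                       paste(eccentricities, collapse = "/"), n_repetitions,
                       if (eyelid) ", eyelid" else ""))
}
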