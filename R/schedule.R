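#' Condition codes used in the gaze protocol
#'
#' The eight eccentric gaze directions in clockwise order starting superior:
#' S, ST, T, IT, I, IN, N, SN; plus `PRIMARY` (straight-ahead baseline) and
#' `CLOSED` (eyelid closure).
#'
#' @format Character vectors.
#' @name condition_codes
NULL

#' @rdname condition_codes
#' @export
GAZE_LABELS <- c("S", "ST", "T", "IT", "I", "IN", "N", "SN")

#' @rdname condition_codes
#' @export
EPOCH_LABELS <- c(GAZE_LABELS, "PRIMARY", "CLOSED")

.ECCENTRICITIES <- c(10, 20, 25)

#' Experiment schedule: ordered labelled epochs
#'
#' An `epoch_schedule` lists the ordered, non-overlapping epochs of one
#' session: condition label, gaze eccentricity in degrees (0 for `PRIMARY`
#' and `CLOSED`), half-open interval `[start_s, end_s)` in seconds from
#' session start, and the repetition number of the experiment block.
#'
#' Protocol invariants checked by the constructor: epochs are time-ordered
#' and non-overlapping; every gaze or `CLOSED` epoch is immediately preceded
#' by a `PRIMARY` baseline epoch; within each eccentricity x repetition block
#' the gaze sequence is a prefix of the clockwise order S, ST, T, IT, I, IN,
#' N, SN followed by the closing control S.
#'
#' @param epochs Data frame with columns `label`, `eccentricity_deg`,
#'   `start_s`, `end_s`, `repetition`.
#' @param patient_id Patient identifier.
#' @param metadata Free-text session metadata.
#' @param validate Check protocol invariants (default `TRUE`).
#' @return An object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(epochs, patient_id = "P01", metadata = "",
                           validate = TRUE) {
  need <- c("label", "eccentricity_deg", "start_s", "end_s", "repetition")
  if (!all(need %in% names(epochs)))
    stop("epochs must have columns: ", paste(need, collapse = ", "))
  epochs <- as.data.frame(epochs)[, need]
  epochs$label <- as.character(epochs$label)
  for (cc in need[-1L]) epochs[[cc]] <- as.numeric(epochs[[cc]])
  epochs$ordinal <- seq_len(nrow(epochs))
  sch <- structure(
    list(patient_id = as.character(patient_id), epochs = epochs,
         metadata = as.character(metadata)),
    class = "epoch_schedule")
  if (validate) validate_schedule(sch)
  sch
}

#' Validate the protocol invariants of a schedule
#'
#' @param schedule An [epoch_schedule()].
#' @return The schedule, invisibly; stops with an informative error on the
#'   first violated invariant.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  ep <- schedule$epochs
  if (!nrow(ep)) stop("schedule has no epochs")
  bad <- setdiff(unique(ep$label), EPOCH_LABELS)
  if (length(bad))
    stop("unknown epoch label(s) ", paste(bad, collapse = ", "),
         "; allowed codes: ", paste(EPOCH_LABELS, collapse = ", "))
  if (anyNA(ep$start_s) || anyNA(ep$end_s) || anyNA(ep$eccentricity_deg) ||
      anyNA(ep$repetition))
    stop("schedule contains missing values")
  if (any(ep$end_s <= ep$start_s))
    stop("every epoch must satisfy end_s > start_s (epoch ",
         which(ep$end_s <= ep$start_s)[1L], ")")
  if (is.unsorted(ep$start_s, strictly = TRUE))
    stop("epochs must be strictly time-ordered")
  if (nrow(ep) > 1L && any(ep$start_s[-1L] < ep$end_s[-nrow(ep)] - 1e-9))
    stop("epochs overlap (epoch ",
         which(ep$start_s[-1L] < ep$end_s[-nrow(ep)] - 1e-9)[1L] + 1L, ")")
  zero_ecc <- ep$label %in% c("PRIMARY", "CLOSED")
  if (any(ep$eccentricity_deg[zero_ecc] != 0))
    stop("PRIMARY and CLOSED epochs must have eccentricity 0")
  gaze <- ep$label %in% GAZE_LABELS
  if (any(!ep$eccentricity_deg[gaze] %in% .ECCENTRICITIES))
    stop("gaze epochs must have eccentricity in {",
         paste(.ECCENTRICITIES, collapse = ", "), "}")
  # baseline alternation: each gaze/CLOSED epoch directly follows a PRIMARY
  need_base <- which(ep$label != "PRIMARY")
  prev_primary <- c(FALSE, ep$label[-nrow(ep)] == "PRIMARY")
  viol <- need_base[!prev_primary[need_base]]
  if (length(viol))
    stop("epoch ", viol[1L], " (", ep$label[viol[1L]],
         ") is not immediately preceded by a PRIMARY baseline epoch")
  # clockwise order within each eccentricity x repetition block
  ref <- c(GAZE_LABELS, "S")
  gz <- ep[gaze, , drop = FALSE]
  if (nrow(gz)) {
    key <- interaction(gz$eccentricity_deg, gz$repetition, drop = TRUE)
    for (k in levels(key)) {
      seqk <- gz$label[key == k]
      if (!identical(seqk, ref[seq_along(seqk)]))
        stop("gaze epochs in block ", k,
             " do not follow the clockwise protocol order ",
             "S, ST, T, IT, I, IN, N, SN (+ closing control S)")
    }
  }
  invisible(schedule)
}

#' @export
print.epoch_schedule <- function(x, ...) {
  ep <- x$epochs
  cat(sprintf("<epoch_schedule> patient %s: %d epochs (%d gaze, %d PRIMARY, %d CLOSED), %.0f s\n",
              x$patient_id, nrow(ep), sum(ep$label %in% GAZE_LABELS),
              sum(ep$label == "PRIMARY"), sum(ep$label == "CLOSED"),
              max(ep$end_s)))
  invisible(x)
}

#' Read an experiment schedule from CSV
#'
#' Expects columns `label,eccentricity_deg,start_s,end_s,repetition`
#' (comment lines `#` allowed, with optional `# patient_id:` metadata).
#' Protocol invariants are validated on read.
#'
#' @param path Path to the schedule file.
#' @param patient_id Optional patient id override.
#' @return An [epoch_schedule()].
#' @export
read_schedule <- function(path, patient_id = NULL) {
  if (!file.exists(path)) stop("schedule file not found: ", path)
  meta <- .parse_hash_metadata(readLines(path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("label", "eccentricity_deg", "start_s", "end_s", "repetition")
  if (!all(need %in% names(df)))
    stop("schedule header must name columns: ", paste(need, collapse = ", "))
  pid <- patient_id %||% meta$patient_id %||%
    sub("\\.[^.]*$", "", basename(path))
  epoch_schedule(df, patient_id = pid,
                 metadata = meta$metadata %||% "")
}

#' Write an experiment schedule to CSV
#'
#' @param schedule An [epoch_schedule()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "epoch_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# patient_id: %s", schedule$patient_id), con)
  ep <- schedule$epochs[, c("label", "eccentricity_deg", "start_s", "end_s",
                            "repetition")]
  utils::write.table(ep, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
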