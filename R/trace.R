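#' Telemetry trace of one recording session
#'
#' An `iop_trace` holds the timestamped pressure samples of one continuous
#' recording: sample times in seconds from session start and IOP in mm Hg,
#' at a nominal rate of about 9 Hz. Times must be strictly increasing; the
#' trace may contain gaps (antenna dropout) which are never interpolated.
#'
#' @param time_s Numeric vector, seconds from session start, strictly
#'   increasing.
#' @param iop Numeric vector of IOP samples (mm Hg), finite, same length as
#'   `time_s`.
#' @param patient_id Opaque patient identifier.
#' @param nominal_rate Nominal sampling rate in Hz (default 9).
#' @return An object of class `iop_trace`.
#' @export
#' @examples
#' tr <- iop_trace(time_s = (0:26) / 9, iop = rep(16, 27))
#' tr
iop_trace <- function(time_s, iop, patient_id = "P01", nominal_rate = 9) {
  time_s <- as.numeric(time_s)
  iop <- as.numeric(iop)
  if (length(time_s) != length(iop))
    stop("time_s and iop must have the same length")
  if (anyNA(time_s) || (length(time_s) && any(!is.finite(time_s))))
    stop("time_s must be finite")
  if (length(iop) && any(!is.finite(iop)))
    stop("iop must be finite (drop NaN/NA samples before constructing)")
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  if (!is.numeric(nominal_rate) || nominal_rate <= 0)
    stop("nominal_rate must be a positive number")
  structure(
    list(patient_id = as.character(patient_id),
         time_s = time_s, iop = iop,
         nominal_rate = as.numeric(nominal_rate)),
    class = "iop_trace")
}

#' @export
print.iop_trace <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf("<iop_trace> patient %s: %d samples", x$patient_id, n))
  if (n) {
    cat(sprintf(", %.1f-%.1f s, IOP %.1f-%.1f mm Hg (nominal %g Hz)",
                min(x$time_s), max(x$time_s), min(x$iop), max(x$iop),
                x$nominal_rate))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.iop_trace <- function(x) length(x$time_s)

#' Read a telemetry trace from a delimited text file
#'
#' Expects a comma-separated file with a header naming a time column
#' (`time_s`) and a pressure column (`iop_mmhg`); lines starting with `#` are
#' comments and may carry `# key: value` metadata (`patient_id`,
#' `nominal_rate`) as written by [write_iop_trace()]. Rows with missing (NaN)
#' pressure are dropped with a warning reporting the count; non-numeric rows
#' raise a parse error naming the offending line; non-monotonic timestamps
#' raise a validation error.
#'
#' @param path Path to the trace file.
#' @param patient_id Optional override of the patient id (otherwise taken
#'   from file metadata, falling back to the file name).
#' @param nominal_rate Nominal sampling rate in Hz; file metadata wins if
#'   present.
#' @return An [iop_trace()].
#' @export
read_iop_trace <- function(path, patient_id = NULL, nominal_rate = 9) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  meta <- .parse_hash_metadata(lines)
  body <- grep("^[[:space:]]*#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) < 1L) stop("trace file has no data rows: ", path)
  header <- strsplit(trimws(lines[body[1L]]), ",")[[1L]]
  header <- trimws(tolower(header))
  t_col <- match("time_s", header)
  p_col <- match("iop_mmhg", header)
  if (is.na(t_col) || is.na(p_col))
    stop("trace header must name columns 'time_s' and 'iop_mmhg'; got: ",
         paste(header, collapse = ", "))
  rows <- body[-1L]
  if (!length(rows)) stop("trace file has a header but no samples: ", path)
  parts <- strsplit(trimws(lines[rows]), ",")
  nfld <- lengths(parts)
  bad <- which(nfld < max(t_col, p_col))
  if (length(bad))
    stop(sprintf("malformed trace row at line %d of %s", rows[bad[1L]], path))
  tm <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", t_col)))
  pr_raw <- trimws(vapply(parts, `[[`, "", p_col))
  pr <- suppressWarnings(as.numeric(pr_raw))
  if (anyNA(tm))
    stop(sprintf("malformed time value at line %d of %s",
                 rows[which(is.na(tm))[1L]], path))
  bad_pr <- is.na(pr) & !(toupper(pr_raw) %in% c("NA", "NAN", ""))
  if (any(bad_pr))
    stop(sprintf("malformed pressure value at line %d of %s",
                 rows[which(bad_pr)[1L]], path))
  drop <- !is.finite(pr)
  if (any(drop)) {
    warning(sprintf("dropped %d sample(s) with missing pressure in %s",
                    sum(drop), path))
    tm <- tm[!drop]; pr <- pr[!drop]
  }
  if (length(tm) > 1L && any(diff(tm) <= 0))
    stop("non-monotonic timestamps in ", path)
  pid <- patient_id %||% meta$patient_id %||%
    sub("\\.[^.]*$", "", basename(path))
  rate <- as.numeric(meta$nominal_rate %||% nominal_rate)
  iop_trace(tm, pr, patient_id = pid, nominal_rate = rate)
}

#' Write a telemetry trace to a delimited text file
#'
#' Writes `# key: value` metadata comment lines followed by a
#' `time_s,iop_mmhg` table. [read_iop_trace()] restores the trace up to
#' floating-point formatting.
#'
#' @param trace An [iop_trace()].
#' @param path Output file path.
#' @param digits Significant digits used when formatting samples.
#' @return `path`, invisibly.
#' @export
write_iop_trace <- function(trace, path, digits = 10) {
  stopifnot(inherits(trace, "iop_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# patient_id: %s", trace$patient_id),
    sprintf("# nominal_rate: %s", format(trace$nominal_rate, digits = digits)),
    "time_s,iop_mmhg",
    paste(format(trace$time_s, digits = digits, trim = TRUE, scientific = FALSE),
          format(trace$iop, digits = digits, trim = TRUE, scientific = FALSE),
          sep = ",")), con)
  invisible(path)
}

#' Quality report on a trace: effective rate and dropout gaps
#'
#' Reports the median inter-sample interval (hence the effective sampling
#' rate) and enumerates gaps longer than three nominal sampling intervals,
#' i.e. stretches of lost telemetry.
#'
#' @param trace An [iop_trace()]; must be non-empty.
#' @param tol_rate Fractional tolerance on the effective rate relative to the
#'   nominal rate (default 0.1).
#' @return A list of class `trace_report` with elements `n_samples`,
#'   `duration_s`, `median_dt`, `effective_rate`, `rate_ok`, `n_gaps`, and a
#'   data frame `gaps` (`start_s`, `end_s`, `length_s`).
#' @export
validate_trace <- function(trace, tol_rate = 0.1) {
  stopifnot(inherits(trace, "iop_trace"))
  n <- length(trace$time_s)
  if (n == 0L) stop("empty trace")
  dt <- diff(trace$time_s)
  med <- if (length(dt)) stats::median(dt) else NA_real_
  eff <- if (is.finite(med) && med > 0) 1 / med else NA_real_
  thr <- 3 / trace$nominal_rate
  g <- which(dt > thr)
  gaps <- data.frame(start_s = trace$time_s[g], end_s = trace$time_s[g + 1L],
                     length_s = dt[g])
  structure(list(
    patient_id = trace$patient_id,
    n_samples = n,
    duration_s = if (n > 1L) diff(range(trace$time_s)) else 0,
    median_dt = med,
    effective_rate = eff,
    rate_ok = is.finite(eff) &&
      abs(eff - trace$nominal_rate) <= tol_rate * trace$nominal_rate,
    n_gaps = length(g),
    gaps = gaps), class = "trace_report")
}

#' @export
print.trace_report <- function(x, ...) {
  cat(sprintf("<trace_report> %s: %d samples over %.1f s, effective rate %.2f Hz (%s), %d gap(s)\n",
              x$patient_id, x$n_samples, x$duration_s, x$effective_rate,
              if (isTRUE(x$rate_ok)) "within tolerance" else "OUT OF TOLERANCE",
              x$n_gaps))
  if (x$n_gaps) print(x$gaps)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_hash_metadata <- function(lines) {
  m <- grep("^[[:space:]]*#", lines, value = TRUE)
  out <- list()
  for (ln in m) {
    kv <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*\\S)\\s*$", ln))[[1L]]
    if (length(kv) == 3L) out[[kv[2L]]] <- kv[3L]
  }
  out
}
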