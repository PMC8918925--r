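#' RR-interval series for one patient
#'
#' Container for one patient's consecutive RR intervals with a class label
#' and the clock time of the first beat.  Beat times are derived from the
#' intervals themselves (cumulative sum), so a series is fully reproducible
#' from the interval list alone.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param rr Numeric vector of consecutive RR intervals in milliseconds,
#'   all strictly positive, length at least 2.
#' @param label Class label, one of `"AF-HF"` (AF-induced heart failure)
#'   or `"control"`.
#' @param start_clock Time of day of the first beat, in seconds since
#'   midnight.  Defaults to 08:00:00, the usual start of a 24-hour Holter
#'   recording.
#'
#' @return An object of class `rr_series`: a list with elements
#'   `patient_id`, `label`, `start_clock`, `rr` (ms) and `beat_times`
#'   (seconds since recording start at which each interval ends).
#' @export
#' @examples
#' s <- rr_series("p1", rr = c(800, 810, 790), label = "control")
#' length(s$rr)
rr_series <- function(patient_id, rr, label = c("control", "AF-HF"),
                      start_clock = 8 * 3600) {
  label <- match.arg(label, c("control", "AF-HF"))
  rr <- as.numeric(rr)
  if (length(rr) < 2)
    stop("an RR series needs at least 2 beats (got ", length(rr), ")")
  if (anyNA(rr) || any(rr <= 0))
    stop("all RR intervals must be positive and non-missing")
  if (!is.numeric(start_clock) || start_clock < 0 || start_clock >= 86400)
    stop("start_clock must be in [0, 86400) seconds since midnight")
  structure(
    list(patient_id = as.character(patient_id),
         label = label,
         start_clock = as.numeric(start_clock),
         rr = rr,
         beat_times = cumsum(rr) / 1000),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> patient %s [%s]: %d beats, %.1f min, start %s\n",
              x$patient_id, x$label, length(x$rr),
              sum(x$rr) / 60000, format_clock(x$start_clock)))
  invisible(x)
}

format_clock <- function(sec) {
  sec <- sec %% 86400
  sprintf("%02d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60,
          round(sec %% 60))
}

#' Relative RR-interval series
#'
#' Expresses each RR interval as a percentage of the preceding one,
#' `100 * rr[n] / rr[n-1]` (the ratio convention: equal consecutive
#' intervals give 100).  The result is scale-free: multiplying all RR
#' intervals by a constant leaves it unchanged.  A symmetric variant,
#' `200 * (rr[n] - rr[n-1]) / (rr[n] + rr[n-1])`, is available for
#' compatibility with the relative-RR literature, where beat-to-beat
#' change is normalised by the mean of the two intervals.
#'
#' @param x An `rr_series`, or a bare numeric vector of RR intervals (ms).
#' @param mode `"ratio"` (default) or `"symmetric"`.
#' @return Numeric vector of length `length(rr) - 1`, in percent.
#' @export
#' @examples
#' to_relative(c(800, 800))  # 100
#' to_relative(c(800, 400))  # 50
to_relative <- function(x, mode = c("ratio", "symmetric")) {
  mode <- match.arg(mode)
  rr <- if (inherits(x, "rr_series")) x$rr else as.numeric(rr_of(x))
  if (length(rr) < 2)
    stop("need at least 2 RR intervals to form a relative series")
  n <- length(rr)
  a <- rr[-1]
  b <- rr[-n]
  if (mode == "ratio") 100 * a / b else 200 * (a - b) / (a + b)
}

rr_of <- function(x) {
  if (inherits(x, "rr_segment")) x$rr else x
}

#' Cut an RR series into fixed-duration segments
#'
#' Windows are defined on cumulative RR time (not wall clock): window `k`
#' spans `[k * duration_s, (k + 1) * duration_s)` seconds since the start
#' of the recording, and a beat belongs to the window containing its onset.
#' The trailing partial window is discarded, as are windows with fewer
#' than `min_beats` beats (artifact-dominated windows).
#'
#' @param series An `rr_series`.
#' @param duration_s Window length in seconds (default 300, the standard
#'   short-term HRV recording length).
#' @param min_beats Minimum beat count for a window to be kept
#'   (default 100, i.e. mean RR up to 3 s in a 5-minute window).
#' @return A list of `rr_segment` objects.  Each carries the patient id
#'   and label, its RR subsequence, its start clock time (seconds since
#'   midnight), its index in the recording, and a circadian tag
#'   (`"day"` for starts in \[08:00, 22:00), `"night"` otherwise).
#' @export
segment_series <- function(series, duration_s = 300, min_beats = 100) {
  stopifnot(inherits(series, "rr_series"), duration_s > 0)
  rr <- series$rr
  onset <- c(0, series$beat_times[-length(rr)])  # onset of each interval
  total <- sum(rr) / 1000
  n_win <- floor(total / duration_s)
  if (n_win < 1) return(list())
  win <- floor(onset / duration_s)  # 0-based window of each beat
  keep <- win < n_win
  segs <- split(which(keep), win[keep])
  out <- vector("list", n_win)
  for (k in seq_len(n_win)) {
    idx <- segs[[as.character(k - 1)]]
    if (is.null(idx) || length(idx) < min_beats) next
    start_clock <- (series$start_clock + (k - 1) * duration_s) %% 86400
    out[[k]] <- structure(
      list(patient_id = series$patient_id,
           label = series$label,
           segment_idx = k,
           rr = rr[idx],
           start_clock = start_clock,
           circadian_tag = circadian_tag(start_clock),
           duration_s = duration_s),
      class = "rr_segment")
  }
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf("<rr_segment> patient %s [%s] #%d: %d beats, %s, start %s\n",
              x$patient_id, x$label, x$segment_idx, length(x$rr),
              x$circadian_tag, format_clock(x$start_clock)))
  invisible(x)
}

#' Circadian tag of a clock time
#'
#' Daytime is \[08:00, 22:00) and nighttime \[22:00, 24:00) plus
#' \[00:00, 08:00), matching the acquisition protocol of 24-hour Holter
#' studies that report day and night performance separately.  Windows are
#' half-open, so a segment starting exactly at 22:00:00 is night.
#'
#' @param start_clock Seconds since midnight.
#' @return `"day"` or `"night"`.
#' @export
circadian_tag <- function(start_clock) {
  ifelse(start_clock %% 86400 >= 8 * 3600 & start_clock %% 86400 < 22 * 3600,
         "day", "night")
}

#' Filter segments by circadian window
#'
#' @param segments A list of `rr_segment` objects.
#' @param window One of `"day"`, `"night"`, `"full"`.  A segment is
#'   assigned by its start time.
#' @return The filtered list.
#' @export
circadian_filter <- function(segments, window = c("full", "day", "night")) {
  window <- match.arg(window)
  if (window == "full") return(segments)
  tags <- vapply(segments, `[[`, character(1), "circadian_tag")
  segments[tags == window]
}

#' Read RR-interval series from a delimited text table
#'
#' Expects columns `patient_id`, `label`, `rr_ms` and optionally
#' `clock_time` (the time of day of the patient's first beat, `HH:MM:SS`
#' or seconds since midnight; only the first row per patient is used).
#' Row order within a patient is preserved.  Rows with missing or
#' non-positive RR are dropped with a reported count; patients left with
#' fewer than 2 beats are skipped with a warning.
#'
#' @param path Path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param sep Field separator.
#' @return A list of `rr_series`, with attribute `dropped_rows` giving
#'   the number of rejected rows.
#' @export
read_rr_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "label", "rr_ms")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(df$rr_ms) | df$rr_ms <= 0
  n_drop <- sum(bad)
  if (n_drop > 0) {
    message(n_drop, " row(s) with missing or non-positive rr_ms dropped")
    df <- df[!bad, , drop = FALSE]
  }
  out <- list()
  for (pid in unique(df$patient_id)) {
    rows <- df[df$patient_id == pid, , drop = FALSE]
    if (nrow(rows) < 2) {
      warning("patient ", pid, " has fewer than 2 beats; skipped")
      next
    }
    start_clock <- 8 * 3600
    if ("clock_time" %in% names(rows))
      start_clock <- parse_clock(rows$clock_time[1])
    out[[as.character(pid)]] <-
      rr_series(pid, rows$rr_ms, label = rows$label[1],
                start_clock = start_clock)
  }
  attr(out, "dropped_rows") <- n_drop
  out
}

parse_clock <- function(x) {
  if (is.na(x) || identical(as.character(x), ""))
    return(8 * 3600)  # recordings run 8 a.m. to 8 a.m. by default
  if (is.numeric(x)) return(x %% 86400)
  parts <- as.numeric(strsplit(as.character(x), ":", fixed = TRUE)[[1]])
  if (length(parts) == 1 && !is.na(parts)) return(parts %% 86400)
  if (length(parts) < 2 || anyNA(parts))
    stop("cannot parse clock time: ", x)
  (parts[1] * 3600 + parts[2] * 60 + if (length(parts) > 2) parts[3] else 0) %%
    86400
}

#' Write a segment collection to long-format CSV
#'
#' One row per beat, columns `patient_id, segment_idx, circadian_tag,
#' start_clock, beat_idx, rr_ms`.
#'
#' @param segments List of `rr_segment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  rows <- lapply(segments, function(s)
    data.frame(patient_id = s$patient_id,
               segment_idx = s$segment_idx,
               circadian_tag = s$circadian_tag,
               start_clock = s$start_clock,
               beat_idx = seq_along(s$rr),
               rr_ms = s$rr))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a cohort of RR series to the package's CSV dialect
#'
#' @param cohort List of `rr_series`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rr_table <- function(cohort, path) {
  rows <- lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id,
               label = s$label,
               rr_ms = s$rr,
               clock_time = format_clock(s$start_clock)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
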