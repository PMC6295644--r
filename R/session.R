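#' Multi-channel physiological session records
#'
#' A `session_record` holds one participant-session's multi-channel time
#' series on a shared 0.1 Hz (default) time base: a data frame of channel
#' values (`NA` = missing sample), optional per-sample experimental-phase
#' labels, and identifying metadata. Phase labels partition a prefix of
#' the record into `baseline_rest`, `chamber_rest`, `cycling`, `recovery`.
#'
#' @param channels Data frame (or named list of equal-length numeric
#'   vectors) of channel values; column names follow the
#'   `<modality>_<site>` convention (see [channel_spec()]).
#' @param participant_id Opaque participant label.
#' @param session_id Session number (1 or 2).
#' @param sample_period_s Seconds between samples (default 10, i.e. 0.1 Hz).
#' @param phase Optional per-sample phase labels (character, `NA`
#'   allowed), or a data frame of half-open intervals with columns
#'   `phase`, `start`, `end` (0-based indices, `[start, end)`).
#' @return An object of class `session_record` with elements `channels`
#'   (data frame), `phase` (character or `NULL`), `participant_id`,
#'   `session_id`, `sample_period_s`.
#' @examples
#' rec <- session_record(
#'   data.frame(heart_rate = c(70, 72, 75), rectal_temp = c(37, 37, 37.1)),
#'   participant_id = "P01", session_id = 1
#' )
#' session_length(rec)
#' @export
session_record <- function(channels, participant_id = "P?", session_id = 1L,
                           sample_period_s = 10, phase = NULL) {
  channels <- as.data.frame(channels, optional = TRUE)
  if (anyDuplicated(names(channels))) {
    stop("duplicated channel columns: ",
         paste(unique(names(channels)[duplicated(names(channels))]), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(channels)
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (!is.numeric(v)) stop("channel '", nm, "' is not numeric", call. = FALSE)
    if (any(is.infinite(v))) stop("channel '", nm, "' contains non-finite values",
                                  call. = FALSE)
  }
  if (is.data.frame(phase)) phase <- phase_labels_from_intervals(phase, n)
  if (!is.null(phase)) {
    phase <- as.character(phase)
    if (length(phase) != n) stop("phase labels must match record length", call. = FALSE)
  }
  stopifnot(sample_period_s > 0)
  structure(list(channels = channels, phase = phase,
                 participant_id = as.character(participant_id),
                 session_id = as.integer(session_id),
                 sample_period_s = sample_period_s),
            class = "session_record")
}

phase_labels_from_intervals <- function(intervals, n) {
  stopifnot(all(c("phase", "start", "end") %in% names(intervals)))
  o <- order(intervals$start)
  intervals <- intervals[o, ]
  if (any(intervals$end < intervals$start) ||
      any(intervals$start[-1] < intervals$end[-nrow(intervals)])) {
    stop("phase intervals must be ordered and non-overlapping", call. = FALSE)
  }
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(intervals))) {
    idx <- seq.int(intervals$start[i] + 1L, length.out = intervals$end[i] - intervals$start[i])
    lab[idx] <- intervals$phase[i]
  }
  lab
}

#' @rdname session_record
#' @param record A `session_record`.
#' @export
session_length <- function(record) nrow(record$channels)

#' @rdname session_record
#' @return `session_time` returns the time of each sample in seconds from
#'   session start (0-based).
#' @export
session_time <- function(record) {
  (seq_len(session_length(record)) - 1) * record$sample_period_s
}

#' @rdname session_record
#' @return `session_phases` returns the half-open phase intervals
#'   (`phase`, `start`, `end`; 0-based, `[start, end)`) derived from the
#'   per-sample labels, or a zero-row frame if no phases are annotated.
#' @export
session_phases <- function(record) {
  empty <- data.frame(phase = character(), start = integer(), end = integer())
  if (is.null(record$phase)) return(empty)
  lab <- record$phase
  present <- !is.na(lab)
  if (!any(present)) return(empty)
  r <- rle(lab[present])
  ends <- cumsum(r$lengths)
  data.frame(phase = r$values,
             start = c(0L, ends[-length(ends)]),
             end = ends)
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s/session %d: %d samples x %d channels @ %gs>\n",
              x$participant_id, x$session_id, session_length(x),
              ncol(x$channels), x$sample_period_s))
  if (!is.null(x$phase)) {
    ph <- session_phases(x)
    cat("  phases:", paste(sprintf("%s[%d,%d)", ph$phase, ph$start, ph$end),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Read and write session CSV files
#'
#' Sessions are exchanged as wide UTF-8 CSV: a `time_s` column, an
#' optional `phase` column, then one column per channel named
#' `<modality>_<site>`. Missing samples are empty cells. Metadata
#' (`participant_id`, `session_id`) travels in optional columns of the
#' same name (constant within a file) so that a session round-trips.
#'
#' @param path File path.
#' @param participant_id,session_id Overrides for metadata absent from
#'   the file.
#' @return `read_session` returns a [session_record()].
#' @export
read_session <- function(path, participant_id = NULL, session_id = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df))) {
    stop("duplicated channel columns in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column in ", path, call. = FALSE)
  time_s <- suppressWarnings(as.numeric(df$time_s))
  if (nrow(df) > 1) {
    dt <- diff(time_s)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      stop("non-monotone or unparseable time_s column in ", path, call. = FALSE)
    }
    period <- dt[1]
    if (any(abs(dt - period) > 1e-6 * max(1, period))) {
      stop("irregular sampling in time_s column of ", path, call. = FALSE)
    }
  } else {
    period <- 10
  }
  meta_cols <- c("time_s", "phase", "participant_id", "session_id")
  phase <- if ("phase" %in% names(df)) {
    p <- as.character(df$phase)
    p[!nzchar(p) | is.na(p)] <- NA_character_
    p
  } else NULL
  pid <- participant_id %||%
    (if ("participant_id" %in% names(df) && nrow(df)) as.character(df$participant_id[1]) else "P?")
  sid <- session_id %||%
    (if ("session_id" %in% names(df) && nrow(df)) df$session_id[1] else 1L)
  chan <- df[setdiff(names(df), meta_cols)]
  for (nm in names(chan)) {
    chan[[nm]] <- suppressWarnings(as.numeric(chan[[nm]]))  # unparseable -> NA
  }
  session_record(chan, participant_id = pid, session_id = sid,
                 sample_period_s = if (nrow(df) > 1) period else 10,
                 phase = phase)
}

#' @rdname read_session
#' @param record A [session_record()].
#' @return `write_session` invisibly returns `path`.
#' @export
write_session <- function(record, path) {
  df <- data.frame(time_s = session_time(record))
  df$participant_id <- rep(record$participant_id, nrow(df))
  df$session_id <- rep(record$session_id, nrow(df))
  if (!is.null(record$phase)) df$phase <- record$phase
  df <- cbind(df, record$channels)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complete-case filtering
#'
#' Restricts a session to the time points at which every required
#' channel has a present value, so that all parameters align; time
#' points with any missing required sample are excluded.
#'
#' @param record A [session_record()].
#' @param required Character vector of required channel names (default:
#'   every channel in the record).
#' @return A list with `record` (the filtered copy) and `mask` (logical
#'   keep-vector over the original time base).
#' @examples
#' rec <- session_record(data.frame(heart_rate = c(70, NA, 75),
#'                                  rectal_temp = c(37, 37, NA)))
#' complete_case_filter(rec)$mask
#' @export
complete_case_filter <- function(record, required = names(record$channels)) {
  missing_ch <- setdiff(required, names(record$channels))
  if (length(missing_ch)) {
    stop("required channel(s) absent from record: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  keep <- rep(TRUE, session_length(record))
  for (nm in required) keep <- keep & !is.na(record$channels[[nm]])
  out <- record
  out$channels <- record$channels[keep, , drop = FALSE]
  rownames(out$channels) <- NULL
  if (!is.null(record$phase)) out$phase <- record$phase[keep]
  list(record = out, mask = keep)
}
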