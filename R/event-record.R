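#' Construct an event record for one operant session
#'
#' An event record holds the timestamped event stream of a single
#' subject-session: nose-pokes on the active and inactive ports, individual
#' licks registered by the lickometer, and sipper extensions/retractions.
#' Timestamps are seconds from session start, carried at millisecond
#' precision (operant hardware samples at 1 kHz).
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param session_id Session identifier (coerced to character).
#' @param events A data frame with columns `time_s` (numeric seconds) and
#'   `kind` (one of `"active_poke"`, `"inactive_poke"`, `"lick"`,
#'   `"sipper_extend"`, `"sipper_retract"`).
#' @param duration_s Session duration in seconds (default 3600, a one-hour
#'   session).
#' @param validate Run [validate_event_record()] on the result (default TRUE).
#'
#' @return An object of class `event_record`: a list with elements
#'   `subject_id`, `session_id`, `duration_s` and `events` (a tibble sorted
#'   by time).
#' @export
#' @examples
#' rec <- event_record("m1", "d1",
#'   events = data.frame(time_s = c(1, 2, 2.5),
#'                       kind = c("active_poke", "lick", "lick")))
#' rec
event_record <- function(subject_id, session_id, events,
                         duration_s = 3600, validate = TRUE) {
  events <- tibble::as_tibble(events)
  if (!all(c("time_s", "kind") %in% names(events))) {
    abort("`events` must have columns `time_s` and `kind`.",
          class = "starpheno_schema_error")
  }
  events$time_s <- as.numeric(events$time_s)
  events$kind <- as.character(events$kind)
  events <- events[order(events$time_s), c("time_s", "kind")]
  rec <- structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         duration_s = as.numeric(duration_s),
         events = events),
    class = "event_record")
  if (validate) validate_event_record(rec)
  rec
}

#' Validate an event record
#'
#' Checks the structural invariants of a session event stream: known event
#' kinds, timestamps within `[0, duration_s]`, non-decreasing times, and
#' strict alternation of sipper extensions and retractions starting with an
#' extension.
#'
#' @param rec An [event_record()].
#' @return `rec`, invisibly, if valid; otherwise an error of class
#'   `starpheno_validation_error` naming the offending session.
#' @export
validate_event_record <- function(rec) {
  stopifnot(inherits(rec, "event_record"))
  ev <- rec$events
  who <- sprintf("subject '%s', session '%s'", rec$subject_id, rec$session_id)
  bad_kind <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(bad_kind) > 0) {
    abort(sprintf("Unknown event kind(s) %s in %s.",
                  paste0("'", bad_kind, "'", collapse = ", "), who),
          class = "starpheno_validation_error")
  }
  if (nrow(ev) > 0) {
    if (anyNA(ev$time_s)) {
      abort(sprintf("Missing event times in %s.", who),
            class = "starpheno_validation_error")
    }
    if (min(ev$time_s) < 0 || max(ev$time_s) > rec$duration_s) {
      abort(sprintf(
        "Event times outside [0, %g] s in %s.", rec$duration_s, who),
        class = "starpheno_validation_error")
    }
    if (is.unsorted(ev$time_s)) {
      abort(sprintf("Event times not sorted in %s.", who),
            class = "starpheno_validation_error")
    }
  }
  sip <- ev$kind[ev$kind %in% c("sipper_extend", "sipper_retract")]
  if (length(sip) > 0) {
    expected <- rep(c("sipper_extend", "sipper_retract"),
                    length.out = length(sip))
    if (!identical(sip, expected)) {
      abort(sprintf(
        "Sipper events must strictly alternate extend/retract (starting with extend) in %s.",
        who),
        class = "starpheno_validation_error")
    }
  }
  invisible(rec)
}

#' @export
print.event_record <- function(x, ...) {
  counts <- table(factor(x$events$kind, levels = EVENT_KINDS))
  cat(sprintf("<event_record> subject %s, session %s (%g s)\n",
              x$subject_id, x$session_id, x$duration_s))
  cat(sprintf("  %d events: %s\n", nrow(x$events),
              paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                    collapse = ", ")))
  invisible(x)
}

#' Read a long-format operant event log
#'
#' Reads a delimited text log with one row per behavioral event and returns
#' one validated [event_record()] per subject-session. Required columns are
#' `subject`, `session`, `time_s` and `kind`; extra columns (e.g. `epoch`)
#' are carried along in the per-record `events` tibble. Malformed rows
#' (unparsable time, unknown kind) are reported with their line numbers.
#'
#' @param file Path to a delimited text file with a header row.
#' @param delim Field delimiter (default `","`).
#' @param duration_s Session duration in seconds applied to every record
#'   (default 3600).
#' @param debounce_s Collapse licks closer together than this many seconds
#'   into a single lick (lickometer contact chatter). Default `NULL`
#'   disables debouncing; 0.02 is a typical value for real hardware logs.
#'
#' @return A named list of `event_record` objects, named
#'   `"<subject>/<session>"`.
#' @export
read_event_log <- function(file, delim = ",", duration_s = 3600,
                           debounce_s = NULL) {
  log <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  needed <- c("subject", "session", "time_s", "kind")
  missing <- setdiff(needed, names(log))
  if (length(missing) > 0) {
    abort(sprintf("Event log is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  if (nrow(log) == 0) return(list())
  time_s <- suppressWarnings(as.numeric(log$time_s))
  bad <- which(is.na(time_s) | !(log$kind %in% EVENT_KINDS))
  if (length(bad) > 0) {
    # +1 for the header row so numbers match the file as seen in an editor
    abort(sprintf("Malformed event rows at line(s): %s.",
                  paste(bad + 1L, collapse = ", ")),
          class = "starpheno_parse_error")
  }
  log$time_s <- time_s
  keys <- split(seq_len(nrow(log)),
                paste(log$subject, log$session, sep = "/"))
  recs <- lapply(keys, function(idx) {
    chunk <- log[idx, ]
    if (!is.null(debounce_s)) {
      chunk <- debounce_licks(chunk, min_gap_s = debounce_s)
    }
    event_record(chunk$subject[[1]], chunk$session[[1]],
                 events = chunk[, c("time_s", "kind")],
                 duration_s = duration_s)
  })
  recs[order(names(recs))]
}

# Collapse lick events separated by less than min_gap_s (instrument chatter);
# other event kinds pass through untouched.
debounce_licks <- function(events, min_gap_s = 0.02) {
  lick_idx <- which(events$kind == "lick")
  if (length(lick_idx) < 2) return(events)
  lick_idx <- lick_idx[order(events$time_s[lick_idx])]
  keep <- c(TRUE, diff(events$time_s[lick_idx]) >= min_gap_s)
  drop_idx <- lick_idx[!keep]
  out <- if (length(drop_idx) > 0) events[-drop_idx, , drop = FALSE] else events
  out[order(out$time_s), , drop = FALSE]
}
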