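ACQ_PHASES <- c("magazine", "criteria1", "criteria2", "discrimination")

#' Evaluate the operant acquisition state machine
#'
#' Replays a subject's acquisition sessions through the phased training
#' protocol. Sessions during acquisition terminate at 100 licks or one
#' hour, whichever comes first, and phases advance on performance criteria:
#'
#' * **magazine**: sipper constantly available; advance the day after the
#'   lick cap is first reached.
#' * **criteria1** (FR 1, 30 s access): advance once the lick cap is
#'   reached on two consecutive days.
#' * **criteria2** (FR 1, 10 s access): same two-consecutive-day cap rule.
#' * **discrimination** (FR 5, 10 s access): acquired once the subject
#'   shows >= 70% active-side responding *and* reaches the lick cap, on two
#'   consecutive sessions.
#'
#' Failing to meet the current phase's criterion on three consecutive
#' sessions reverts the subject to the previous phase (consecutive-success
#' counters reset); a third revert event removes the subject from the
#' experiment. In the magazine phase, which has no predecessor, three
#' consecutive failures count as a revert event with the phase unchanged.
#'
#' @param sessions A data frame in chronological order with columns
#'   `cap_reached` (logical: did the session hit the lick cap) and
#'   `discrimination` (numeric active-side fraction, `NA` when undefined or
#'   not applicable; only consulted in the discrimination phase). An `NA`
#'   discrimination index counts as a failed session.
#' @param di_criterion Discrimination threshold (default 0.70).
#'
#' @return An object of class `acquisition_outcome`: list with
#'   `status` (`"acquired"`, `"removed"` or `"in_progress"`),
#'   `sessions_to_acquire` (count, `NA` unless acquired), `reverts_used`
#'   (0–3), and `phase_trajectory` (character vector giving the phase each
#'   session was run under).
#' @export
evaluate_acquisition <- function(sessions, di_criterion = 0.70) {
  sessions <- as.data.frame(sessions)
  if (nrow(sessions) > 0 && !all(c("cap_reached", "discrimination") %in%
                                 names(sessions))) {
    abort("`sessions` needs columns `cap_reached` and `discrimination`.",
          class = "starpheno_schema_error")
  }
  phase <- 1L            # index into ACQ_PHASES
  streak_pass <- 0L      # consecutive sessions meeting the phase criterion
  streak_fail <- 0L      # consecutive sessions failing it
  reverts <- 0L
  trajectory <- character(0)
  status <- "in_progress"
  sessions_to_acquire <- NA_integer_

  needed_passes <- function(phase) if (phase == 1L) 1L else 2L

  for (i in seq_len(nrow(sessions))) {
    trajectory <- c(trajectory, ACQ_PHASES[[phase]])
    cap <- isTRUE(sessions$cap_reached[[i]])
    di <- sessions$discrimination[[i]]
    pass <- if (phase == 4L) cap && !is.na(di) && di >= di_criterion else cap
    if (pass) {
      streak_pass <- streak_pass + 1L
      streak_fail <- 0L
      if (streak_pass >= needed_passes(phase)) {
        if (phase == 4L) {
          status <- "acquired"
          sessions_to_acquire <- i
          break
        }
        phase <- phase + 1L
        streak_pass <- 0L
      }
    } else {
      streak_fail <- streak_fail + 1L
      streak_pass <- 0L
      if (streak_fail >= 3L) {
        reverts <- reverts + 1L
        if (reverts >= 3L) {
          status <- "removed"
          break
        }
        phase <- max(1L, phase - 1L)
        streak_fail <- 0L
      }
    }
  }

  structure(
    list(status = status,
         sessions_to_acquire = sessions_to_acquire,
         reverts_used = reverts,
         phase_trajectory = trajectory),
    class = "acquisition_outcome")
}

#' @export
print.acquisition_outcome <- function(x, ...) {
  cat(sprintf("<acquisition_outcome> status = %s", x$status))
  if (!is.na(x$sessions_to_acquire)) {
    cat(sprintf(" after %d sessions", x$sessions_to_acquire))
  }
  cat(sprintf(", reverts used = %d\n", x$reverts_used))
  if (length(x$phase_trajectory) > 0) {
    cat("  trajectory:", paste(x$phase_trajectory, collapse = " -> "), "\n")
  }
  invisible(x)
}
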