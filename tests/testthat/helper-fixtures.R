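# Shared fixtures and independent oracles, built in code at test time.

# Minimal intake table: one session per condition per subject.
make_intake <- function(subjects, alcohol_gkg, quinine_gkg) {
  dplyr::bind_rows(
    tibble::tibble(subject = subjects, condition = "alcohol_only",
                   session_index = 1L, intake_gkg = alcohol_gkg),
    tibble::tibble(subject = subjects, condition = "alcohol_quinine",
                   session_index = 1L, intake_gkg = quinine_gkg))
}

# Random cohort with the full 3 + 4 session design (uses current RNG).
random_intake_table <- function(n) {
  subjects <- sprintf("s%03d", seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(
      subject = rep(subjects, each = 3), condition = "alcohol_only",
      session_index = rep(1:3, n),
      intake_gkg = rlnorm(3 * n, log(2), 0.4)),
    tibble::tibble(
      subject = rep(subjects, each = 4), condition = "alcohol_quinine",
      session_index = rep(4:7, n),
      intake_gkg = rlnorm(4 * n, log(1), 0.6)))
}

# Straight transcription of the published phenotype rules (with scores at
# exactly 100 treated as not above average), independent of
# classify_subject().
transcribe_rules <- function(alcohol_pct, quinine_pct) {
  out <- character(length(alcohol_pct))
  for (i in seq_along(alcohol_pct)) {
    out[[i]] <- if (quinine_pct[[i]] > 100) {
      "Compulsive"
    } else if (alcohol_pct[[i]] > 100) {
      "High"
    } else {
      "Low"
    }
  }
  out
}

# Independent Spearman oracle: midranks, then the Pearson product-moment
# formula written out by hand.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Hand-traced acquisition session sequences with expected outcomes.
# cap = cap_reached, di = discrimination index (NA outside discrimination).
acq_case <- function(cap, di, status, sessions_to_acquire, reverts,
                     trajectory) {
  list(sessions = data.frame(cap_reached = cap, discrimination = di),
       status = status, sessions_to_acquire = sessions_to_acquire,
       reverts = reverts, trajectory = trajectory)
}

acquisition_fixtures <- function() {
  P <- TRUE; F_ <- FALSE
  list(
    straight_through = acq_case(
      cap = c(P, P, P, P, P, P, P),
      di = c(NA, NA, NA, NA, NA, 0.8, 0.8),
      status = "acquired", sessions_to_acquire = 7L, reverts = 0L,
      trajectory = c("magazine", "criteria1", "criteria1", "criteria2",
                     "criteria2", "discrimination", "discrimination")),
    empty = acq_case(
      cap = logical(0), di = numeric(0),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 0L, trajectory = character(0)),
    magazine_two_fails = acq_case(
      cap = c(F_, F_), di = c(NA, NA),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 0L, trajectory = c("magazine", "magazine")),
    magazine_three_fails_revert = acq_case(
      cap = c(F_, F_, F_), di = c(NA, NA, NA),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L, trajectory = rep("magazine", 3)),
    magazine_nine_fails_removed = acq_case(
      cap = rep(F_, 9), di = rep(NA, 9),
      status = "removed", sessions_to_acquire = NA_integer_,
      reverts = 3L, trajectory = rep("magazine", 9)),
    criteria1_nonconsecutive = acq_case(
      # P | P F P P: the fail resets the two-consecutive window
      cap = c(P, P, F_, P, P), di = rep(NA, 5),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 0L,
      trajectory = c("magazine", rep("criteria1", 4))),
    criteria2_revert_to_criteria1 = acq_case(
      cap = c(P, P, P, F_, F_, F_), di = rep(NA, 6),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1",
                     rep("criteria2", 3))),
    revert_then_readvance = acq_case(
      cap = c(P, P, P, F_, F_, F_, P, P), di = rep(NA, 8),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1",
                     rep("criteria2", 3), "criteria1", "criteria1")),
    discrimination_low_di_fails = acq_case(
      cap = c(P, P, P, P, P, P, P, P),
      di = c(NA, NA, NA, NA, NA, 0.6, 0.6, 0.6),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1", "criteria2",
                     "criteria2", rep("discrimination", 3))),
    discrimination_na_di_fails = acq_case(
      cap = c(P, P, P, P, P, P, P, P),
      di = c(NA, NA, NA, NA, NA, NA, NA, NA),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1", "criteria2",
                     "criteria2", rep("discrimination", 3))),
    discrimination_cap_required = acq_case(
      cap = c(P, P, P, P, P, F_, F_, F_),
      di = c(NA, NA, NA, NA, NA, 0.9, 0.9, 0.9),
      status = "in_progress", sessions_to_acquire = NA_integer_,
      reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1", "criteria2",
                     "criteria2", rep("discrimination", 3))),
    revert_readvance_acquire = acq_case(
      cap = c(P, P, P, P, P, F_, F_, F_, P, P, P, P),
      di = c(NA, NA, NA, NA, NA, 0.6, 0.5, 0.6, NA, NA, 0.75, 0.70),
      status = "acquired", sessions_to_acquire = 12L, reverts = 1L,
      trajectory = c("magazine", "criteria1", "criteria1", "criteria2",
                     "criteria2", rep("discrimination", 3),
                     "criteria2", "criteria2",
                     "discrimination", "discrimination")),
    three_reverts_removed = acq_case(
      cap = c(P, P, P, F_, F_, F_, F_, F_, F_, P, P, F_, F_, F_),
      di = rep(NA, 14),
      status = "removed", sessions_to_acquire = NA_integer_,
      reverts = 3L,
      trajectory = c("magazine", "criteria1", "criteria1",
                     rep("criteria2", 3), rep("criteria1", 3),
                     "magazine", rep("criteria1", 4))))
}
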