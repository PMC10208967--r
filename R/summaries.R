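#' Summarize one session's event stream into per-session scalars
#'
#' Aggregates an [event_record()] to the scalar measures used by the
#' phenotyping, stability and screen stages: response counts by port, lick
#' count, reinforcers earned (sipper presentations), and g/kg intake.
#'
#' @param rec An [event_record()].
#' @param session_index Ordinal day within the epoch.
#' @param epoch One of `"acquisition"`, `"pre_binge"`, `"binge"`,
#'   `"phenotyping"`, `"extinction"`, `"conditioned_reinforcement"`.
#' @param condition One of `"alcohol_only"`, `"alcohol_quinine"`, `"dry"`,
#'   `"water_choice"`. Dry sessions (extinction / conditioned
#'   reinforcement) have zero intake by definition.
#' @param quinine_mM Quinine concentration in the bottle (mM; 0 when
#'   absent).
#' @param consumed_volume_mL Volumetric consumption measurement for the
#'   session (mL).
#' @param weight_g Same-day subject weight in grams (mice are weighed at
#'   the end of each session).
#' @param ethanol_vv Ethanol fraction, v/v (default 0.15).
#'
#' @return A one-row tibble with columns `subject_id`, `session_id`,
#'   `session_index`, `epoch`, `condition`, `quinine_mM`,
#'   `consumed_volume_mL`, `weight_g`, `intake_gkg`, `active_responses`,
#'   `inactive_responses`, `licks`, `reinforcers`.
#' @export
summarize_session <- function(rec, session_index = NA_integer_,
                              epoch = "phenotyping",
                              condition = "alcohol_only",
                              quinine_mM = 0,
                              consumed_volume_mL = NA_real_,
                              weight_g = NA_real_,
                              ethanol_vv = 0.15) {
  validate_event_record(rec)
  kinds <- rec$events$kind
  n_of <- function(k) sum(kinds == k)
  intake <- if (condition %in% c("dry", "water_choice")) {
    0
  } else if (is.na(consumed_volume_mL) || is.na(weight_g)) {
    NA_real_
  } else {
    compute_intake_gkg(consumed_volume_mL, ethanol_vv, weight_g)
  }
  tibble::tibble(
    subject_id = rec$subject_id,
    session_id = rec$session_id,
    session_index = as.integer(session_index),
    epoch = epoch,
    condition = condition,
    quinine_mM = quinine_mM,
    consumed_volume_mL = consumed_volume_mL,
    weight_g = weight_g,
    intake_gkg = intake,
    active_responses = n_of("active_poke"),
    inactive_responses = n_of("inactive_poke"),
    licks = n_of("lick"),
    reinforcers = n_of("sipper_extend"))
}

#' Summarize every session in an event log against session metadata
#'
#' Convenience wrapper joining a list of event records (from
#' [read_event_log()]) with a per-session metadata table and calling
#' [summarize_session()] on each.
#'
#' @param records Named list of [event_record()]s.
#' @param meta Data frame with columns `subject`, `session` and any of
#'   `session_index`, `epoch`, `condition`, `quinine_mM`,
#'   `consumed_volume_mL`, `weight_g`. One row per subject-session.
#' @param ethanol_vv Ethanol fraction, v/v.
#' @return A tibble with one row per session (see [summarize_session()]).
#' @export
summarize_sessions <- function(records, meta, ethanol_vv = 0.15) {
  meta <- tibble::as_tibble(meta)
  if (!all(c("subject", "session") %in% names(meta))) {
    abort("`meta` needs columns `subject` and `session`.",
          class = "starpheno_schema_error")
  }
  key <- paste(meta$subject, meta$session, sep = "/")
  if (anyDuplicated(key)) {
    abort("`meta` has duplicate subject/session rows.",
          class = "starpheno_schema_error")
  }
  get_meta <- function(row, col, default) {
    if (col %in% names(meta) && !is.na(meta[[col]][[row]])) {
      meta[[col]][[row]]
    } else default
  }
  purrr::map_dfr(records, function(rec) {
    row <- match(paste(rec$subject_id, rec$session_id, sep = "/"), key)
    if (is.na(row)) {
      abort(sprintf("No metadata for subject '%s', session '%s'.",
                    rec$subject_id, rec$session_id),
            class = "starpheno_schema_error")
    }
    summarize_session(
      rec,
      session_index = get_meta(row, "session_index", NA_integer_),
      epoch = get_meta(row, "epoch", "phenotyping"),
      condition = get_meta(row, "condition", "alcohol_only"),
      quinine_mM = get_meta(row, "quinine_mM", 0),
      consumed_volume_mL = get_meta(row, "consumed_volume_mL", NA_real_),
      weight_g = get_meta(row, "weight_g", NA_real_),
      ethanol_vv = ethanol_vv)
  })
}
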