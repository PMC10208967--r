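#' Build a phenotyping intake table from session summaries
#'
#' Selects the sessions of one epoch and maps them to the two phenotyping
#' conditions: unpunished alcohol sessions and quinine-adulterated
#' (punished) sessions. Sessions are mapped by their `condition` column,
#' not by position, so shortened or re-ordered designs reuse the same
#' machinery.
#'
#' @param summaries Session summary tibble (see [summarize_sessions()] or
#'   the simulator), with columns `subject_id`, `epoch`, `condition`,
#'   `session_index`, `intake_gkg`.
#' @param epoch Which epoch to phenotype on (default `"phenotyping"`, the
#'   post-binge sessions used for group assignment).
#' @return A tibble with columns `subject`, `condition`
#'   (`"alcohol_only"` / `"alcohol_quinine"`), `session_index`,
#'   `intake_gkg` — the long-format intake table consumed by
#'   [normalize_scores()] and friends.
#' @export
intake_from_summaries <- function(summaries, epoch = "phenotyping") {
  summaries <- tibble::as_tibble(summaries)
  needed <- c("subject_id", "epoch", "condition", "intake_gkg")
  missing <- setdiff(needed, names(summaries))
  if (length(missing) > 0) {
    abort(sprintf("Summaries are missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  out <- summaries[summaries$epoch == epoch &
                     summaries$condition %in%
                     c("alcohol_only", "alcohol_quinine"), ]
  tibble::tibble(
    subject = as.character(out$subject_id),
    condition = out$condition,
    session_index = if ("session_index" %in% names(out)) {
      out$session_index
    } else NA_integer_,
    intake_gkg = out$intake_gkg)
}

# Validate a long intake table and return per-subject condition means in
# the original subject order. Subjects missing a condition entirely are
# dropped with a warning.
subject_condition_means <- function(intake) {
  intake <- tibble::as_tibble(intake)
  needed <- c("subject", "condition", "intake_gkg")
  missing <- setdiff(needed, names(intake))
  if (length(missing) > 0) {
    abort(sprintf("Intake table is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  bad <- setdiff(unique(intake$condition),
                 c("alcohol_only", "alcohol_quinine"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  if (any(intake$intake_gkg < 0, na.rm = TRUE)) {
    abort("Intakes must be non-negative.", class = "starpheno_domain_error")
  }
  means <- intake |>
    dplyr::filter(!is.na(.data$intake_gkg)) |>
    dplyr::group_by(.data$subject, .data$condition) |>
    dplyr::summarise(mean_gkg = mean(.data$intake_gkg), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_gkg")
  for (col in c("alcohol_only", "alcohol_quinine")) {
    if (!col %in% names(means)) means[[col]] <- NA_real_
  }
  incomplete <- is.na(means$alcohol_only) | is.na(means$alcohol_quinine)
  if (any(incomplete)) {
    warn(sprintf(
      "Dropping %d subject(s) with no sessions in one condition: %s.",
      sum(incomplete),
      paste(means$subject[incomplete], collapse = ", ")))
    means <- means[!incomplete, ]
  }
  # restore input subject order
  means[order(match(means$subject, unique(intake$subject))), ]
}

#' Group-normalized phenotyping scores
#'
#' Computes, for each subject, intake as a percent of the sample mean in
#' each condition: the subject's mean g/kg over the unpunished alcohol
#' sessions divided by the mean of all subjects' means, times 100; and the
#' analogous score over the quinine-adulterated sessions. By construction
#' the cohort mean of each score is exactly 100.
#'
#' @param intake Long intake table (see [intake_from_summaries()]):
#'   columns `subject`, `condition`, `intake_gkg`.
#' @return A tibble with columns `subject`, `alcohol_gkg`, `quinine_gkg`
#'   (the per-subject condition means) and `alcohol_pct`, `quinine_pct`
#'   (percent of the cohort mean).
#' @export
normalize_scores <- function(intake) {
  means <- subject_condition_means(intake)
  if (nrow(means) < 2) {
    abort("Normalization needs at least 2 subjects with both conditions.",
          class = "starpheno_degenerate_cohort_error")
  }
  denom_a <- mean(means$alcohol_only)
  denom_q <- mean(means$alcohol_quinine)
  if (denom_a == 0 || denom_q == 0) {
    abort("Cohort mean intake is zero in one condition; scores undefined.",
          class = "starpheno_degenerate_cohort_error")
  }
  tibble::tibble(
    subject = means$subject,
    alcohol_gkg = means$alcohol_only,
    quinine_gkg = means$alcohol_quinine,
    alcohol_pct = 100 * means$alcohol_only / denom_a,
    quinine_pct = 100 * means$alcohol_quinine / denom_q)
}

#' Classify subjects into drinking phenotypes
#'
#' Applies the Low/High/Compulsive Drinker rules to normalized scores:
#' a subject with above-average punished intake (`quinine_pct > 100`) is a
#' Compulsive Drinker regardless of its unpunished score; otherwise,
#' above-average unpunished intake (`alcohol_pct > 100`) makes a High
#' Drinker, and below-average intake in both conditions a Low Drinker.
#' Scores exactly at 100 are treated as not above average, so a score of
#' exactly 100 resolves to the less severe label.
#'
#' @param alcohol_pct,quinine_pct Normalized scores (percent of cohort
#'   mean). Vectorized.
#' @return A factor with levels `Low`, `High`, `Compulsive`.
#' @export
#' @examples
#' classify_subject(c(80, 120, 60), c(70, 70, 130))
classify_subject <- function(alcohol_pct, quinine_pct) {
  if (any(!is.finite(alcohol_pct)) || any(!is.finite(quinine_pct))) {
    abort("Scores must be finite.", class = "starpheno_domain_error")
  }
  if (any(alcohol_pct < 0) || any(quinine_pct < 0)) {
    abort("Scores must be non-negative.", class = "starpheno_domain_error")
  }
  label <- ifelse(quinine_pct > 100, "Compulsive",
                  ifelse(alcohol_pct > 100, "High", "Low"))
  factor(label, levels = PHENOTYPE_LEVELS)
}

#' Phenotype a cohort
#'
#' Runs [normalize_scores()] and [classify_subject()] over a cohort's
#' phenotyping-epoch intake table. The returned scores are also the
#' recommended scatter coordinates for visualization (x = `quinine_pct`,
#' y = `alcohol_pct`).
#'
#' @param intake Long intake table (see [intake_from_summaries()]).
#' @param min_n Minimum cohort size below which a warning is emitted
#'   (default 15, the recommended minimum sample for stable phenotyping;
#'   the computation itself runs for any n >= 2).
#' @return A tibble with columns `subject`, `alcohol_gkg`, `quinine_gkg`,
#'   `alcohol_pct`, `quinine_pct`, `label`.
#' @export
phenotype_cohort <- function(intake, min_n = 15) {
  scores <- normalize_scores(intake)
  if (nrow(scores) < min_n) {
    warn(sprintf(
      "Cohort has %d subjects; phenotype assignment is unstable below %d subjects.",
      nrow(scores), min_n))
  }
  scores$label <- classify_subject(scores$alcohol_pct, scores$quinine_pct)
  scores
}
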