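#' Rank-correlation screen of brain analytes against drinking behavior
#'
#' Correlates each analyte's concentration, separately by brain region,
#' with the normalized behavior metrics from phenotyping (percent-of-mean
#' intake for alcohol-only and alcohol+quinine sessions) using Spearman's
#' rank correlation with midranks for ties. Intended for screens such as 23
#' neurotransmitters/precursors/metabolites quantified in mPFC and dPAG.
#'
#' P-values use the exact permutation null distribution when `n <= 10`
#' and there are no ties, and the t approximation otherwise. No
#' multiple-testing correction is applied by default (significance stars
#' mark unadjusted p-values); set `p_adjust = "BH"` for
#' Benjamini–Hochberg-adjusted q-values in an extra column.
#'
#' @param analytes Long tibble with columns `subject`, `region`, `analyte`,
#'   `concentration` (amount per mg protein; `NA` allowed).
#' @param behavior Phenotyping result (see [phenotype_cohort()]) or any
#'   data frame with a `subject` column and the metric columns.
#' @param metrics Behavior columns to screen against (default
#'   `c("alcohol_pct", "quinine_pct")`).
#' @param min_pairs Minimum complete pairs per correlation (default 5);
#'   cells with fewer, or with a constant variable, are returned with `NA`
#'   statistics and `computed = FALSE`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return A tibble with one row per (region, analyte, metric): columns
#'   `region`, `analyte`, `metric`, `r`, `p`, `n`, `computed`, `sig`
#'   (`""`, `"*"`, `"**"`, `"***"` at 0.05/0.01/0.001), and `q` when
#'   adjusted.
#' @export
correlate_analytes <- function(analytes, behavior,
                               metrics = c("alcohol_pct", "quinine_pct"),
                               min_pairs = 5, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  analytes <- tibble::as_tibble(analytes)
  behavior <- tibble::as_tibble(behavior)
  needed <- c("subject", "region", "analyte", "concentration")
  missing <- setdiff(needed, names(analytes))
  if (length(missing) > 0) {
    abort(sprintf("Analyte table is missing column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  missing_m <- setdiff(c("subject", metrics), names(behavior))
  if (length(missing_m) > 0) {
    abort(sprintf("Behavior table is missing column(s): %s.",
                  paste(missing_m, collapse = ", ")),
          class = "starpheno_schema_error")
  }
  if (any(analytes$concentration < 0, na.rm = TRUE)) {
    abort("Concentrations must be non-negative.",
          class = "starpheno_domain_error")
  }

  cells <- analytes |>
    dplyr::distinct(.data$region, .data$analyte) |>
    tidyr::crossing(metric = metrics)

  rows <- purrr::pmap_dfr(cells, function(region, analyte, metric) {
    sub <- analytes[analytes$region == region &
                      analytes$analyte == analyte, ]
    merged <- dplyr::inner_join(
      sub[, c("subject", "concentration")],
      behavior[, c("subject", metric)],
      by = "subject")
    x <- merged$concentration
    y <- merged[[metric]]
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < min_pairs || sd(x) == 0 || sd(y) == 0) {
      return(tibble::tibble(region = region, analyte = analyte,
                            metric = metric, r = NA_real_, p = NA_real_,
                            n = n, computed = FALSE))
    }
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = (n <= 10 && !ties)))
    tibble::tibble(region = region, analyte = analyte, metric = metric,
                   r = unname(ct$estimate), p = ct$p.value, n = n,
                   computed = TRUE)
  })
  rows$sig <- dplyr::case_when(
    is.na(rows$p) ~ "",
    rows$p < 0.001 ~ "***",
    rows$p < 0.01 ~ "**",
    rows$p < 0.05 ~ "*",
    TRUE ~ "")
  if (p_adjust == "BH") {
    rows$q <- stats::p.adjust(rows$p, method = "BH")
  }
  rows
}

#' Wide r-matrix from a screen result
#'
#' Reshapes a [correlate_analytes()] result into the analyte-by-column
#' matrix layout used for bubble-plot style visualization (one column per
#' region x metric combination).
#'
#' @param screen A [correlate_analytes()] result.
#' @return A tibble with one row per analyte and one `r` column per
#'   `region.metric` combination.
#' @export
screen_r_matrix <- function(screen) {
  screen |>
    dplyr::mutate(cell = paste(.data$region, .data$metric, sep = ".")) |>
    dplyr::select("analyte", "cell", "r") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "r")
}
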