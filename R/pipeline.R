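#' Write a CSV with a JSON provenance sidecar
#'
#' Every pipeline output file gets a `<file>.provenance.json` sidecar
#' recording the package version, the seed and configuration used, and a
#' schema version, so any artifact can be reproduced from its sidecar.
#'
#' @param x Data frame to write.
#' @param path Output CSV path.
#' @param config List of configuration values to record (seed included).
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, config = list()) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x, path, progress = FALSE)
  prov <- list(
    schema_version = "1",
    package = "starpheno",
    package_version = as.character(packageVersion("starpheno")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Chains the pipeline stages on a configuration list: simulate a cohort
#' (or load session summaries from CSV), phenotype it, run the sample-size
#' stability analysis, and — when analyte data are present — the
#' correlation screen. Identical configuration and seed yield identical
#' outputs.
#'
#' @param config A list (e.g. parsed from a YAML file) with elements:
#'   * `seed` — integer seed (default 1);
#'   * `summaries` — optional path to a session summary CSV; when absent a
#'     cohort is simulated with `cohort` (arguments for [cohort_config()]);
#'   * `epoch` — epoch used for phenotyping (default `"phenotyping"`);
#'   * `min_n` — cohort-size warning threshold (default 15);
#'   * `stability` — optional list with `iterations`, `k_min`, `k_max`,
#'     `tolerance`; stage skipped when absent;
#'   * `analytes` — optional path to an analyte CSV (simulated analytes
#'     are used when a cohort is simulated);
#'   * `outdir` — output directory (no files written when `NULL`).
#' @return A list with elements `phenotypes`, `curve` (or NULL),
#'   `recommended_n` (or NULL), `screen` (or NULL), `cohort` (or NULL),
#'   invisibly when writing files.
#' @export
run_pipeline <- function(config = list()) {
  seed <- config$seed %||% 1
  epoch <- config$epoch %||% "phenotyping"

  cohort <- NULL
  analyte_tbl <- NULL
  if (!is.null(config$summaries)) {
    if (!file.exists(config$summaries)) {
      abort(sprintf("Summary file not found: %s", config$summaries),
            class = "starpheno_io_error")
    }
    summaries <- readr::read_csv(config$summaries, show_col_types = FALSE,
                                 progress = FALSE)
  } else {
    cfg <- do.call(cohort_config, config$cohort %||% list())
    cohort <- simulate_cohort(cfg, seed = seed)
    summaries <- cohort$sessions
    analyte_tbl <- cohort$analytes
  }
  if (!is.null(config$analytes)) {
    if (!file.exists(config$analytes)) {
      abort(sprintf("Analyte file not found: %s", config$analytes),
            class = "starpheno_io_error")
    }
    analyte_tbl <- readr::read_csv(config$analytes, show_col_types = FALSE,
                                   progress = FALSE)
  }

  intake <- intake_from_summaries(summaries, epoch = epoch)
  phenotypes <- phenotype_cohort(intake, min_n = config$min_n %||% 15)

  curve <- NULL
  rec_n <- NULL
  if (!is.null(config$stability)) {
    st <- config$stability
    curve <- mismatch_curve(
      intake,
      k_min = st$k_min %||% 2,
      k_max = st$k_max %||% nrow(phenotypes),
      iterations = st$iterations %||% 100,
      seed = seed)
    rec_n <- recommend_min_n(curve, tolerance = st$tolerance %||% 0.05)
  }

  screen <- NULL
  if (!is.null(analyte_tbl)) {
    screen <- correlate_analytes(analyte_tbl, phenotypes)
  }

  if (!is.null(config$outdir)) {
    prov <- list(seed = seed, epoch = epoch, config = config["cohort"])
    write_output_csv(phenotypes, file.path(config$outdir, "phenotypes.csv"),
                     prov)
    if (!is.null(curve)) {
      write_output_csv(tibble::as_tibble(curve),
                       file.path(config$outdir, "stability_curve.csv"),
                       c(prov, list(recommended_n = rec_n)))
    }
    if (!is.null(screen)) {
      write_output_csv(screen, file.path(config$outdir, "screen.csv"), prov)
    }
    if (!is.null(cohort)) {
      write_output_csv(cohort$sessions,
                       file.path(config$outdir, "sessions.csv"), prov)
      write_output_csv(cohort$truth,
                       file.path(config$outdir, "truth.csv"), prov)
    }
  }

  res <- list(phenotypes = phenotypes, curve = curve,
              recommended_n = rec_n, screen = screen, cohort = cohort)
  if (is.null(config$outdir)) res else invisible(res)
}
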