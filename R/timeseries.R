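#' Cumulative record of events
#'
#' The classic operant-conditioning visualization: a step function counting
#' events over the session. The record is defined at time 0 with value 0 and
#' steps up by one at each event time.
#'
#' @param times Sorted event times in seconds.
#' @param duration_s Session duration; the record is extended flat to this
#'   time so records of equal-length sessions align.
#' @return A tibble with columns `time_s` and `count`, non-decreasing in
#'   `count`, ending at `length(times)`.
#' @export
cumulative_record <- function(times, duration_s = 3600) {
  if (is.unsorted(times)) {
    abort("`times` must be sorted non-decreasing.",
          class = "starpheno_domain_error")
  }
  if (length(times) > 0 && (min(times) < 0 || max(times) > duration_s)) {
    abort("`times` must lie within [0, duration_s].",
          class = "starpheno_domain_error")
  }
  tibble::tibble(
    time_s = c(0, times, duration_s),
    count = c(0, seq_along(times), length(times)))
}

#' Bin event times into fixed-width rate bins
#'
#' Counts events in consecutive half-open bins `[lo, hi)` of width `bin_s`
#' covering `[0, duration_s]`; an event exactly at the session end falls in
#' the last bin. Used at 10 s width for nose-poke responses and 1 s width
#' for licks.
#'
#' @param times Event times in seconds (any order).
#' @param bin_s Bin width in seconds (> 0).
#' @param duration_s Session duration; `ceiling(duration_s / bin_s)` bins
#'   are returned.
#' @return Integer vector of per-bin counts summing to `length(times)`.
#' @export
#' @examples
#' binned_rate(c(0.5, 9.9, 10), bin_s = 10, duration_s = 20)  # c(2, 1)
binned_rate <- function(times, bin_s, duration_s = 3600) {
  if (bin_s <= 0) {
    abort("`bin_s` must be positive.", class = "starpheno_domain_error")
  }
  if (length(times) > 0 && (min(times) < 0 || max(times) > duration_s)) {
    abort("`times` must lie within [0, duration_s].",
          class = "starpheno_domain_error")
  }
  n_bins <- as.integer(ceiling(duration_s / bin_s))
  if (length(times) == 0) return(integer(n_bins))
  idx <- pmin(floor(times / bin_s) + 1L, n_bins)  # t == duration -> last bin
  tabulate(idx, nbins = n_bins)
}

#' Active-side discrimination index
#'
#' Fraction of total nose-poke responses emitted on the active port;
#' >= 0.70 is the acquisition criterion in the discrimination phase.
#'
#' @param active,inactive Response counts (>= 0). Vectorized.
#' @return `active / (active + inactive)`, or `NA` where both counts are
#'   zero (the index is undefined, not zero; an `NA` session counts as a
#'   failed session in acquisition evaluation).
#' @export
discrimination_index <- function(active, inactive) {
  if (any(active < 0 | inactive < 0, na.rm = TRUE)) {
    abort("Counts must be non-negative.", class = "starpheno_domain_error")
  }
  total <- active + inactive
  ifelse(total > 0, active / total, NA_real_)
}

#' Lick microstructure: burst decomposition
#'
#' Partitions a session's lick train into bursts — maximal runs of licks in
#' which every consecutive interlick interval (ILI) is at most the burst
#' threshold. Rodents lick in stereotyped ~6–10 Hz bursts; changes in burst
#' number versus burst size dissociate appetitive and consummatory drive.
#'
#' @param lick_times Sorted lick times in seconds.
#' @param ili_burst_threshold_s Maximum within-burst interlick interval in
#'   seconds (default 0.5).
#' @return An object of class `lick_microstructure`: list with `n_licks`,
#'   `n_bursts`, `burst_sizes` (integer vector summing to `n_licks`),
#'   `mean_burst_size`, and `ili` (the full interlick-interval vector,
#'   length `n_licks - 1`).
#' @export
#' @examples
#' lick_microstructure(c(0, 0.1, 0.2, 1.0, 1.1), 0.5)
lick_microstructure <- function(lick_times, ili_burst_threshold_s = 0.5) {
  if (ili_burst_threshold_s <= 0) {
    abort("`ili_burst_threshold_s` must be positive.",
          class = "starpheno_domain_error")
  }
  if (is.unsorted(lick_times)) {
    abort("`lick_times` must be sorted non-decreasing.",
          class = "starpheno_domain_error")
  }
  n <- length(lick_times)
  if (n == 0) {
    out <- list(n_licks = 0L, n_bursts = 0L, burst_sizes = integer(0),
                mean_burst_size = NA_real_, ili = numeric(0))
  } else {
    ili <- diff(lick_times)
    burst_id <- cumsum(c(1L, as.integer(ili > ili_burst_threshold_s)))
    burst_sizes <- as.integer(tabulate(burst_id))
    out <- list(n_licks = n, n_bursts = length(burst_sizes),
                burst_sizes = burst_sizes,
                mean_burst_size = mean(burst_sizes), ili = ili)
  }
  structure(out, class = "lick_microstructure",
            ili_burst_threshold_s = ili_burst_threshold_s)
}

#' @export
print.lick_microstructure <- function(x, ...) {
  cat(sprintf(
    "<lick_microstructure> %d licks in %d bursts (mean size %.2f; ILI threshold %g s)\n",
    x$n_licks, x$n_bursts,
    if (is.na(x$mean_burst_size)) 0 else x$mean_burst_size,
    attr(x, "ili_burst_threshold_s")))
  invisible(x)
}
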