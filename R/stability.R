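# Integer phenotype codes for the fast resampling path: 1 Low, 2 High,
# 3 Compulsive. Classification of subset S uses the same arithmetic as
# normalize_scores (pct = 100 * x / mean(x[S])) so that S = full cohort
# reproduces the full-sample labels bit-for-bit.
classify_codes <- function(a, q, idx) {
  a_pct <- 100 * a[idx] / mean(a[idx])
  q_pct <- 100 * q[idx] / mean(q[idx])
  ifelse(q_pct > 100, 3L, ifelse(a_pct > 100, 2L, 1L))
}

# Shared setup: per-subject condition means and full-cohort label codes.
stability_setup <- function(intake) {
  means <- subject_condition_means(intake)
  n <- nrow(means)
  if (n < 3) {
    abort("Stability analysis needs at least 3 subjects.",
          class = "starpheno_domain_error")
  }
  list(subjects = means$subject,
       a = means$alcohol_only,
       q = means$alcohol_quinine,
       n = n,
       full_codes = classify_codes(means$alcohol_only,
                                   means$alcohol_quinine,
                                   seq_len(n)))
}

# Evaluate `code` with the global RNG seeded by `seed` (when non-NULL),
# restoring the caller's RNG state afterwards.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Phenotype assignments within a random subsample
#'
#' Draws `k` subjects without replacement, redetermines the group
#' normalization using only the subsample, and classifies the sampled
#' subjects. This is the elementary step of the sample-size stability
#' analysis: labels are relative to the (re-estimated) sample mean, so they
#' can differ from the full-cohort labels.
#'
#' @param intake Long intake table (see [intake_from_summaries()]).
#' @param k Subsample size, `2 <= k <= N`.
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble with columns `subject`, `label` (factor), and
#'   `full_label` (the subject's label under full-cohort normalization).
#' @export
subsample_assignments <- function(intake, k, seed = NULL) {
  setup <- stability_setup(intake)
  if (k < 2 || k > setup$n) {
    abort(sprintf("`k` must be in [2, %d].", setup$n),
          class = "starpheno_domain_error")
  }
  idx <- with_rng(seed, sample.int(setup$n, k))
  codes <- classify_codes(setup$a, setup$q, idx)
  tibble::tibble(
    subject = setup$subjects[idx],
    label = factor(PHENOTYPE_LEVELS[codes], levels = PHENOTYPE_LEVELS),
    full_label = factor(PHENOTYPE_LEVELS[setup$full_codes[idx]],
                        levels = PHENOTYPE_LEVELS))
}

#' Phenotype-stability curve by permutated resampling
#'
#' For each subsample size `k`, repeatedly draws `k` subjects at random,
#' re-runs the phenotyping analysis on the subsample alone (group
#' normalization redetermined each time), and compares the resulting labels
#' to those from the full cohort. The primary statistic is the per-subject
#' empirical probability of changing phenotype assignment: pooled label
#' disagreements divided by `k * iterations`. The fraction of iterations
#' containing at least one disagreement is also reported.
#'
#' @param intake Long intake table (see [intake_from_summaries()]).
#' @param k_min,k_max Range of subsample sizes (defaults 2 and N).
#' @param iterations Independent subsamples per size (default 100).
#' @param seed Integer root seed; per-size substreams are derived from it,
#'   so a fixed seed yields a bit-identical curve.
#' @return An object of class `stability_curve`: a tibble with columns
#'   `k`, `mismatch_prob`, `se` (Monte-Carlo standard error of the
#'   per-iteration mismatch fractions), `any_mismatch_prob`, `iterations`;
#'   attributes carry the seed and cohort size.
#' @export
mismatch_curve <- function(intake, k_min = 2, k_max = NULL,
                           iterations = 100, seed = NULL) {
  setup <- stability_setup(intake)
  k_max <- k_max %||% setup$n
  if (k_min < 2 || k_max > setup$n || k_min > k_max) {
    abort(sprintf("Need 2 <= k_min <= k_max <= %d.", setup$n),
          class = "starpheno_domain_error")
  }
  if (iterations < 1) {
    abort("`iterations` must be >= 1.", class = "starpheno_domain_error")
  }
  ks <- seq.int(k_min, k_max)
  k_seeds <- with_rng(seed, sample.int(.Machine$integer.max, length(ks)))
  rows <- purrr::map2_dfr(ks, k_seeds, function(k, k_seed) {
    frac <- with_rng(if (is.null(seed)) NULL else k_seed, {
      vapply(seq_len(iterations), function(i) {
        idx <- sample.int(setup$n, k)
        mean(classify_codes(setup$a, setup$q, idx) != setup$full_codes[idx])
      }, numeric(1))
    })
    tibble::tibble(
      k = k,
      mismatch_prob = mean(frac),
      se = if (iterations > 1) sd(frac) / sqrt(iterations) else NA_real_,
      any_mismatch_prob = mean(frac > 0),
      iterations = iterations)
  })
  structure(rows, class = c("stability_curve", class(rows)),
            seed = seed, n_subjects = setup$n)
}

#' Exact expected mismatch probability by exhaustive enumeration
#'
#' Enumerates every k-subset of the cohort, computes the fraction of
#' sampled subjects whose subsample label disagrees with their full-cohort
#' label, and averages uniformly over subsets. This is the brute-force
#' quantity that [mismatch_curve()] estimates by Monte Carlo; it is
#' feasible only for small cohorts.
#'
#' @param intake Long intake table.
#' @param k Subsample size, `2 <= k <= N`, with `choose(N, k) <= 1e6`.
#' @return The exact expected per-subject mismatch probability.
#' @export
exact_mismatch <- function(intake, k) {
  setup <- stability_setup(intake)
  if (k < 2 || k > setup$n) {
    abort(sprintf("`k` must be in [2, %d].", setup$n),
          class = "starpheno_domain_error")
  }
  if (choose(setup$n, k) > 1e6) {
    abort("choose(N, k) exceeds 1e6; use mismatch_curve() (Monte Carlo) instead.",
          class = "starpheno_domain_error")
  }
  subsets <- combn(setup$n, k)
  fracs <- apply(subsets, 2, function(idx) {
    mean(classify_codes(setup$a, setup$q, idx) != setup$full_codes[idx])
  })
  mean(fracs)
}

#' Recommend a minimum cohort size from a stability curve
#'
#' Returns the smallest evaluated `k` such that every evaluated size
#' `k' >= k` has a mismatch probability at or below the tolerance — i.e.
#' the sample size from which phenotype assignment stays stable.
#'
#' @param curve A [mismatch_curve()] result (or any data frame with
#'   columns `k` and `mismatch_prob` over a contiguous range of `k`).
#' @param tolerance Maximum acceptable mismatch probability (default
#'   0.05).
#' @return The recommended minimum `k`, or `NA_integer_` if no evaluated
#'   size qualifies.
#' @export
recommend_min_n <- function(curve, tolerance = 0.05) {
  stopifnot(all(c("k", "mismatch_prob") %in% names(curve)))
  ord <- order(curve$k)
  k <- curve$k[ord]
  ok <- curve$mismatch_prob[ord] <= tolerance
  # stable from k onward: ok must hold for this and every later size
  stable_from <- rev(cumprod(rev(ok))) == 1
  if (!any(stable_from)) return(NA_integer_)
  as.integer(k[which(stable_from)[1]])
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf(
    "<stability_curve> N = %d subjects, k = %d..%d, %d iterations/size\n",
    attr(x, "n_subjects"), min(x$k), max(x$k), x$iterations[[1]]))
  NextMethod()
}
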