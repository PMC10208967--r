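fast_cfg <- function(...) {
  cohort_config(event_epochs = character(0), ...)
}

test_that("cohort simulation is reproducible from a single seed", {
  cfg <- fast_cfg(n_subjects = 10)
  a <- simulate_cohort(cfg, seed = 3)
  b <- simulate_cohort(cfg, seed = 3)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$analytes, b$analytes)
  d <- simulate_cohort(cfg, seed = 4)
  expect_false(identical(a$sessions$intake_gkg, d$sessions$intake_gkg))
})

test_that("phenotype draws follow the configured proportions", {
  cfg <- fast_cfg()
  set.seed(61)
  draws <- replicate(4000, simulate_subject(cfg)$phenotype)
  p_hat <- table(factor(draws, c("Low", "High", "Compulsive"))) / 4000
  p_true <- c(19, 5, 17) / 41
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_true(all(abs(p_hat - p_true) < 3 * se))
  # degenerate proportions
  cfg_low <- fast_cfg(phenotype_proportions = c(Low = 1, High = 0,
                                                Compulsive = 0))
  set.seed(62)
  expect_true(all(replicate(20, simulate_subject(cfg_low)$phenotype) ==
                    "Low"))
})

test_that("compulsive retention dominates at every quinine concentration", {
  cfg <- cohort_config()
  set.seed(63)
  subs <- purrr::map_dfr(1:60, function(i) simulate_subject(cfg, i))
  conc <- c(0.25, 0.5, 0.75, 1)
  ret <- function(row) quinine_retention(conc, row$c50_mM, row$slope_mM)
  comp <- subs[subs$phenotype == "Compulsive", ]
  other <- subs[subs$phenotype != "Compulsive", ]
  ret_mat <- function(df) {
    t(vapply(seq_len(nrow(df)), function(i) ret(df[i, ]), numeric(4)))
  }
  min_comp <- apply(ret_mat(comp), 2, min)
  max_other <- apply(ret_mat(other), 2, max)
  expect_true(all(min_comp > max_other))
})

test_that("simulated event streams pass validation and schedule arithmetic", {
  cfg <- cohort_config()
  set.seed(64)
  subj <- simulate_subject(cfg, "m1")
  for (q in c(0, 0.5)) {
    sim <- simulate_session(subj, cfg, condition =
                              if (q > 0) "alcohol_quinine" else "alcohol_only",
                            quinine_mM = q)
    expect_silent(validate_event_record(sim$record))
    ev <- sim$record$events
    windows <- cbind(ev$time_s[ev$kind == "sipper_extend"],
                     ev$time_s[ev$kind == "sipper_retract"])
    pokes <- ev$time_s[ev$kind == "active_poke"]
    in_access <- vapply(pokes, function(p) {
      any(p >= windows[, 1] & p <= windows[, 2])
    }, logical(1))
    eligible <- sum(!in_access)
    expect_equal(sim$summary$reinforcers, floor(eligible / cfg$fr_ratio))
    # licks only occur during access windows
    licks <- ev$time_s[ev$kind == "lick"]
    expect_true(all(vapply(licks, function(l) {
      any(l >= windows[, 1] & l <= windows[, 2])
    }, logical(1))))
  }
})

test_that("the lick cap terminates acquisition-style sessions", {
  cfg <- cohort_config()
  set.seed(65)
  subj <- simulate_subject(cfg, "m1")
  subj$post_gkg <- 4  # enough drive to hit the cap
  sim <- simulate_session(subj, cfg, lick_cap = 100)
  expect_lte(sim$summary$licks, 100)
  expect_lte(sim$record$duration_s, cfg$duration_s)
  expect_equal(sim$summary$licks, 100)
  expect_lt(sim$record$duration_s, cfg$duration_s)
})

test_that("quinine suppression scales mean intake by the retention factor", {
  cfg <- fast_cfg()
  set.seed(66)
  subj <- simulate_subject(cfg, "m1")
  subj$c50_mM <- 0.3; subj$slope_mM <- 0.18
  retention <- starpheno:::quinine_retention(1, subj$c50_mM, subj$slope_mM)
  draws_a <- replicate(400, starpheno:::session_target_gkg(
    subj, cfg, "phenotyping", "alcohol_only", 0))
  draws_q <- replicate(400, starpheno:::session_target_gkg(
    subj, cfg, "phenotyping", "alcohol_quinine", 1))
  ratio <- mean(draws_q) / mean(draws_a)
  se <- ratio * sqrt(sd(draws_q)^2 / mean(draws_q)^2 +
                       sd(draws_a)^2 / mean(draws_a)^2) / sqrt(400)
  expect_lt(abs(ratio - retention), 3 * se)
})

test_that("two-bottle intake is linear in access time with no phenotype effect", {
  cfg <- fast_cfg()
  set.seed(67)
  subj <- simulate_subject(cfg, "m1")
  expect_equal(simulate_two_bottle(subj, cfg, 0)$alcohol_mL, 0)
  g2 <- replicate(300, simulate_two_bottle(subj, cfg, 2)$intake_gkg)
  g4 <- replicate(300, simulate_two_bottle(subj, cfg, 4)$intake_gkg)
  se <- sqrt(sd(g4)^2 / 300 + 4 * sd(g2)^2 / 300)
  expect_lt(abs(mean(g4) - 2 * mean(g2)), 3 * se)
  # equal means across phenotypes by construction
  cohort <- simulate_cohort(fast_cfg(n_subjects = 60), seed = 68)
  tb <- dplyr::left_join(cohort$two_bottle,
                         cohort$truth[, c("subject", "phenotype")],
                         by = "subject")
  tb <- tb[tb$access_h > 0, ]
  fit <- stats::aov(intake_gkg ~ phenotype, data = tb)
  expect_gt(summary(fit)[[1]][["Pr(>F)"]][1], 0.05)
})

test_that("null analyte coupling yields centred correlations", {
  cohort <- simulate_cohort(fast_cfg(analyte_coupling = 0), seed = 69)
  ph <- phenotype_cohort(intake_from_summaries(cohort$sessions))
  res <- correlate_analytes(cohort$analytes, ph)
  expect_lt(abs(mean(res$r)), 0.1)
})
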