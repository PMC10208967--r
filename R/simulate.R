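#' Default analyte panel for the simulated neurochemical screen
#'
#' Twenty-three neurotransmitters, precursors and metabolites quantified
#' per brain region in the screen stage.
#' @export
ANALYTE_PANEL <- c(
  "dopamine", "DOPAC", "HVA", "3-MT", "norepinephrine", "epinephrine",
  "serotonin", "5-HIAA", "tryptophan", "kynurenine", "tyrosine",
  "phenylalanine", "GABA", "glutamate", "glutamine", "aspartate",
  "glycine", "serine", "taurine", "histamine", "histidine", "choline",
  "acetylcholine")

#' Simulator configuration for a synthetic drinking cohort
#'
#' Parameterizes the generative model used to emulate an operant alcohol
#' self-administration cohort with latent Low/High/Compulsive phenotypes:
#' limited between-subject variance before binge exposure, phenotype-scaled
#' amplification afterwards, and a logistic quinine-retention curve per
#' phenotype (Compulsive retention dominating the others at every
#' concentration). All rates and distributions are exposed here; the
#' defaults describe a 41-subject cohort with 19/5/17 phenotype
#' proportions, one-hour FR-10 sessions with 10 s sipper access, and
#' mouse-typical weights and lick volumes.
#'
#' @param n_subjects Cohort size (default 41).
#' @param phenotype_proportions Named numeric (Low, High, Compulsive)
#'   summing to 1; default `c(19, 5, 17) / 41`.
#' @param weight_mean_g,weight_sd_g Body weight distribution (grams).
#' @param ethanol_vv Ethanol fraction, v/v (default 0.15).
#' @param fr_ratio Fixed-ratio response requirement (default 10).
#' @param access_s Sipper access per reinforcer, seconds (default 10).
#' @param duration_s Session length, seconds (default 3600).
#' @param pre_binge_gkg Mean pre-binge per-session intake propensity
#'   (g/kg; common low-variance distribution across phenotypes).
#' @param pre_binge_cv Between-subject CV of the pre-binge propensity.
#' @param amplification Named post-binge multiplier per phenotype
#'   (Low < High ~ Compulsive).
#' @param amplification_cv Between-subject CV of the multiplier.
#' @param session_cv Session-to-session intake CV.
#' @param quinine_c50_mM Named per-phenotype midpoint of the logistic
#'   retention curve (mM); Compulsive far above the tested range.
#' @param quinine_slope_mM Named per-phenotype logistic slope (mM).
#' @param c50_jitter_sdlog Between-subject log-scale jitter on the
#'   midpoint.
#' @param lick_volume_uL,lick_volume_cv Per-lick volume (microliters) and
#'   its CV.
#' @param poke_rate_hz Active-poke rate while engaged (Hz, before vigor
#'   scaling).
#' @param inactive_rate_hz Inactive-poke rate (Hz, before vigor scaling).
#' @param vigor_cv Between-subject CV of response vigor.
#' @param satiety_poke_factor Multiplier on the poke rate after the
#'   session's intake target is consumed.
#' @param refractory_s Pause after sipper retraction before responding
#'   resumes (seconds).
#' @param licks_per_window Mean licks consumed per 10 s access window when
#'   motivated.
#' @param binge_gkg_per_h Mean two-bottle-choice intake rate (g/kg per
#'   hour of access; no phenotype effect by default).
#' @param binge_cv Session CV of two-bottle intake.
#' @param binge_preference Mean alcohol preference in two-bottle choice.
#' @param event_epochs Epochs simulated at event level (full timestamped
#'   logs); other operant epochs get session summaries drawn from the same
#'   latent model. Default `c("pre_binge", "phenotyping")`.
#' @param analyte_coupling Strength of the log-linear coupling between the
#'   coupled analytes and the latent behavior metrics (0 disables all
#'   couplings; default 0.6).
#' @param analyte_noise_sdlog Residual log-scale noise on analyte
#'   concentrations.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 41,
                          phenotype_proportions = c(Low = 19, High = 5,
                                                    Compulsive = 17) / 41,
                          weight_mean_g = 27, weight_sd_g = 2,
                          ethanol_vv = 0.15,
                          fr_ratio = 10, access_s = 10, duration_s = 3600,
                          pre_binge_gkg = 1.8, pre_binge_cv = 0.12,
                          amplification = c(Low = 0.85, High = 1.8,
                                            Compulsive = 1.8),
                          amplification_cv = 0.15,
                          session_cv = 0.15,
                          quinine_c50_mM = c(Low = 0.30, High = 0.35,
                                             Compulsive = 2.0),
                          quinine_slope_mM = c(Low = 0.18, High = 0.18,
                                               Compulsive = 0.6),
                          c50_jitter_sdlog = 0.15,
                          lick_volume_uL = 1.5, lick_volume_cv = 0.2,
                          poke_rate_hz = 0.35, inactive_rate_hz = 0.008,
                          vigor_cv = 0.25,
                          satiety_poke_factor = 0.05,
                          refractory_s = 2,
                          licks_per_window = 55,
                          binge_gkg_per_h = 1.3, binge_cv = 0.25,
                          binge_preference = 0.8,
                          event_epochs = c("pre_binge", "phenotyping"),
                          analyte_coupling = 0.6,
                          analyte_noise_sdlog = 0.35) {
  props <- phenotype_proportions
  if (is.null(names(props)) ||
      !setequal(names(props), PHENOTYPE_LEVELS)) {
    abort("`phenotype_proportions` must be named Low/High/Compulsive.",
          class = "starpheno_domain_error")
  }
  if (abs(sum(props) - 1) > 1e-8 || any(props < 0)) {
    abort("`phenotype_proportions` must be non-negative and sum to 1.",
          class = "starpheno_domain_error")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

# Logistic quinine-retention curve, normalized so retention(0) = 1.
quinine_retention <- function(quinine_mM, c50_mM, slope_mM) {
  f <- function(c) 1 / (1 + exp((c - c50_mM) / slope_mM))
  f(quinine_mM) / f(0)
}

#' Draw one latent subject
#'
#' Samples a subject's latent traits from a [cohort_config()]: phenotype,
#' body weight, pre- and post-binge intake propensities (g/kg per
#' session), quinine-retention curve parameters and response vigor. The
#' post-binge propensity amplifies a common pre-binge distribution by the
#' phenotype's multiplier, so limited initial differences widen with
#' experience; Compulsive subjects' retention curves dominate the other
#' phenotypes' at every quinine concentration.
#'
#' @param cfg A [cohort_config()].
#' @param subject_id Identifier for the subject.
#' @return A one-row tibble of latent traits (`subject`, `phenotype`,
#'   `weight_g`, `pre_gkg`, `post_gkg`, `c50_mM`, `slope_mM`, `vigor`).
#' @export
simulate_subject <- function(cfg, subject_id = "s1") {
  stopifnot(inherits(cfg, "cohort_config"))
  phen <- sample(PHENOTYPE_LEVELS, 1,
                 prob = cfg$phenotype_proportions[PHENOTYPE_LEVELS])
  cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))
  pre <- cfg$pre_binge_gkg *
    rlnorm(1, -cv_to_sdlog(cfg$pre_binge_cv)^2 / 2,
           cv_to_sdlog(cfg$pre_binge_cv))
  amp <- cfg$amplification[[phen]] *
    rlnorm(1, -cv_to_sdlog(cfg$amplification_cv)^2 / 2,
           cv_to_sdlog(cfg$amplification_cv))
  # Compulsive subjects also respond more vigorously
  vigor <- rlnorm(1, -cv_to_sdlog(cfg$vigor_cv)^2 / 2,
                  cv_to_sdlog(cfg$vigor_cv)) *
    if (phen == "Compulsive") 1.25 else 1
  tibble::tibble(
    subject = as.character(subject_id),
    phenotype = phen,
    weight_g = max(18, rnorm(1, cfg$weight_mean_g, cfg$weight_sd_g)),
    pre_gkg = pre,
    post_gkg = pre * amp,
    c50_mM = cfg$quinine_c50_mM[[phen]] * rlnorm(1, 0, cfg$c50_jitter_sdlog),
    slope_mM = cfg$quinine_slope_mM[[phen]],
    vigor = vigor)
}

# Session-level intake target (g/kg) for a subject under a condition.
session_target_gkg <- function(subj, cfg, epoch, condition, quinine_mM) {
  if (condition %in% c("dry", "water_choice")) return(0)
  propensity <- if (epoch == "pre_binge") subj$pre_gkg else subj$post_gkg
  retention <- if (quinine_mM > 0) {
    quinine_retention(quinine_mM, subj$c50_mM, subj$slope_mM)
  } else 1
  cv <- cfg$session_cv
  sdlog <- sqrt(log(1 + cv^2))
  propensity * retention * rlnorm(1, -sdlog^2 / 2, sdlog)
}

# Burst-structured lick train on [start, end], at most n_max licks.
gen_lick_train <- function(start, end, n_max) {
  if (n_max <= 0 || start >= end) return(numeric(0))
  times <- numeric(0)
  t <- start + runif(1, 0.1, 0.5)  # latency to first lick
  while (length(times) < n_max && t < end) {
    size <- 4 + rpois(1, 8)
    ili <- pmax(0.06, rnorm(size, 0.12, 0.015))
    burst <- t + cumsum(c(0, ili))[seq_len(size)]
    burst <- burst[burst < end]
    times <- c(times, burst)
    t <- if (length(burst) > 0) max(burst) else t
    t <- t + 0.4 + rexp(1, 2)  # pause between bursts
  }
  head(times, n_max)
}

#' Simulate one operant self-administration session
#'
#' Generates a full timestamped event stream for a session under a
#' fixed-ratio schedule: active pokes as a renewal process scaled by the
#' subject's vigor, sipper extension on every `fr_ratio`-th ratio-eligible
#' poke with retraction after `access_s`, burst-structured licking during
#' access windows until the session's latent intake target is consumed,
#' and sparse inactive pokes. Pokes emitted while the sipper is extended
#' are logged but not ratio-eligible. If `lick_cap` is set the session
#' terminates when cumulative licks reach the cap (the acquisition-epoch
#' rule), otherwise at `duration_s`.
#'
#' @param subj One-row latent subject tibble from [simulate_subject()].
#' @param cfg A [cohort_config()].
#' @param epoch,condition,quinine_mM,session_index Session metadata (see
#'   [summarize_session()]).
#' @param session_id Session identifier.
#' @param lick_cap Optional lick cap terminating the session early.
#' @return A list with elements `record` (an [event_record()]) and
#'   `summary` (a one-row session summary tibble).
#' @export
simulate_session <- function(subj, cfg, epoch = "phenotyping",
                             condition = "alcohol_only", quinine_mM = 0,
                             session_index = 1L,
                             session_id = paste0(epoch, "_", session_index),
                             lick_cap = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  target_gkg <- session_target_gkg(subj, cfg, epoch, condition, quinine_mM)
  target_volume_mL <- target_gkg * (subj$weight_g / 1000) /
    (cfg$ethanol_vv * ETHANOL_DENSITY_G_PER_ML)
  target_licks <- round(target_volume_mL * 1000 / cfg$lick_volume_uL)

  duration <- cfg$duration_s
  rate <- cfg$poke_rate_hz * subj$vigor
  t <- 0
  eligible <- 0L
  active_t <- numeric(0)
  lick_t <- numeric(0)
  ext_t <- numeric(0)
  ret_t <- numeric(0)
  end_time <- duration
  capped <- FALSE

  while (t < duration && !capped) {
    sated <- length(lick_t) >= target_licks
    r <- rate * if (sated) cfg$satiety_poke_factor else 1
    t <- t + rexp(1, r)
    if (t >= duration) break
    active_t <- c(active_t, t)
    eligible <- eligible + 1L
    if (eligible %% cfg$fr_ratio == 0L) {
      ext <- t + 0.05                      # sipper travel time
      if (ext >= duration) {
        # no room to deliver the earned reinforcer: the completing poke is
        # not registered, keeping reinforcers == floor(eligible / ratio)
        active_t <- head(active_t, -1)
        eligible <- eligible - 1L
        break
      }
      ret <- min(ext + cfg$access_s, duration)
      ext_t <- c(ext_t, ext)
      remaining <- target_licks - length(lick_t)
      win_licks <- if (remaining > 0) {
        gen_lick_train(ext, ret, min(remaining, round(
          cfg$licks_per_window * runif(1, 0.8, 1.2))))
      } else numeric(0)
      if (!is.null(lick_cap) && length(win_licks) > 0 &&
          length(lick_t) + length(win_licks) >= lick_cap) {
        win_licks <- head(win_licks, lick_cap - length(lick_t))
        capped <- TRUE
        end_time <- max(win_licks)
        ret <- end_time                    # sipper retracts at termination
      }
      lick_t <- c(lick_t, win_licks)
      # non-eligible pokes during the access window
      n_in <- rpois(1, rate * 0.2 * (ret - ext))
      if (n_in > 0) active_t <- c(active_t, sort(runif(n_in, ext, ret)))
      ret_t <- c(ret_t, ret)
      t <- ret + cfg$refractory_s
    }
  }

  n_inact <- rpois(1, cfg$inactive_rate_hz * subj$vigor * end_time)
  inactive_t <- sort(runif(n_inact, 0, end_time))

  events <- tibble::tibble(
    time_s = c(active_t, inactive_t, lick_t, ext_t, ret_t),
    kind = c(rep("active_poke", length(active_t)),
             rep("inactive_poke", length(inactive_t)),
             rep("lick", length(lick_t)),
             rep("sipper_extend", length(ext_t)),
             rep("sipper_retract", length(ret_t))))
  events$time_s <- round(events$time_s, 3)  # 1 kHz hardware clock
  rec <- event_record(subj$subject, session_id, events,
                      duration_s = round(end_time, 3))

  consumed_mL <- if (length(lick_t) == 0) 0 else {
    sdlog <- sqrt(log(1 + cfg$lick_volume_cv^2))
    sum(rlnorm(length(lick_t), log(cfg$lick_volume_uL) - sdlog^2 / 2,
               sdlog)) / 1000
  }
  summary <- summarize_session(
    rec, session_index = session_index, epoch = epoch,
    condition = condition, quinine_mM = quinine_mM,
    consumed_volume_mL = consumed_mL, weight_g = subj$weight_g,
    ethanol_vv = cfg$ethanol_vv)
  list(record = rec, summary = summary)
}

# Summary-only session draw from the same latent model (no event stream);
# used for epochs outside cfg$event_epochs.
draw_session_summary <- function(subj, cfg, epoch, condition, quinine_mM,
                                 session_index) {
  target_gkg <- session_target_gkg(subj, cfg, epoch, condition, quinine_mM)
  volume_mL <- target_gkg * (subj$weight_g / 1000) /
    (cfg$ethanol_vv * ETHANOL_DENSITY_G_PER_ML)
  licks <- round(volume_mL * 1000 / cfg$lick_volume_uL)
  reinforcers <- ceiling(licks / cfg$licks_per_window)
  active <- reinforcers * cfg$fr_ratio +
    rpois(1, 5 + 20 * subj$vigor)
  tibble::tibble(
    subject_id = subj$subject,
    session_id = paste0(epoch, "_", session_index),
    session_index = as.integer(session_index),
    epoch = epoch, condition = condition, quinine_mM = quinine_mM,
    consumed_volume_mL = volume_mL, weight_g = subj$weight_g,
    intake_gkg = compute_intake_gkg(volume_mL, cfg$ethanol_vv,
                                    subj$weight_g),
    active_responses = as.integer(active),
    inactive_responses = as.integer(
      rpois(1, cfg$inactive_rate_hz * subj$vigor * cfg$duration_s)),
    licks = as.integer(licks),
    reinforcers = as.integer(reinforcers))
}

#' Simulate a two-bottle choice day
#'
#' Home-cage free access to an alcohol bottle and a water bottle. Intake
#' scales linearly with access duration, alcohol preference is high, and —
#' by default — total alcohol intake does not differ by phenotype
#' (individual drinking differences re-emerge only under operant testing).
#'
#' @param subj One-row latent subject tibble.
#' @param cfg A [cohort_config()].
#' @param access_h Hours of bottle access (0 on abstinence days).
#' @return A one-row tibble: `subject`, `access_h`, `alcohol_mL`,
#'   `water_mL`, `preference`, `intake_gkg`.
#' @export
simulate_two_bottle <- function(subj, cfg, access_h) {
  if (access_h < 0) {
    abort("`access_h` must be non-negative.",
          class = "starpheno_domain_error")
  }
  if (access_h == 0) {
    return(tibble::tibble(subject = subj$subject, access_h = 0,
                          alcohol_mL = 0, water_mL = 0,
                          preference = NA_real_, intake_gkg = 0))
  }
  sdlog <- sqrt(log(1 + cfg$binge_cv^2))
  gkg <- cfg$binge_gkg_per_h * access_h * rlnorm(1, -sdlog^2 / 2, sdlog)
  alcohol_mL <- gkg * (subj$weight_g / 1000) /
    (cfg$ethanol_vv * ETHANOL_DENSITY_G_PER_ML)
  pref <- min(0.99, max(0.01, rnorm(1, cfg$binge_preference, 0.07)))
  water_mL <- alcohol_mL * (1 - pref) / pref
  tibble::tibble(
    subject = subj$subject, access_h = access_h,
    alcohol_mL = alcohol_mL, water_mL = water_mL,
    preference = preference_ratio(alcohol_mL, water_mL),
    intake_gkg = gkg)
}

# Analyte couplings: which (region, analyte) pairs track which latent
# behavior metric. Monoamine tone tracks alcohol intake in both regions;
# excitatory/inhibitory amino acids in dPAG track punished intake.
default_analyte_couplings <- function() {
  tibble::tibble(
    region = c(rep("mPFC", 3), rep("dPAG", 6), rep("dPAG", 4)),
    analyte = c("serotonin", "5-HIAA", "DOPAC",
                "serotonin", "5-HIAA", "dopamine", "DOPAC", "GABA",
                "glutamate",
                "glutamate", "GABA", "glutamine", "aspartate"),
    metric = c(rep("alcohol", 9), rep("quinine", 4)))
}

# Simulate the analyte table (subject x region x analyte) with log-linear
# couplings to the standardized latent behavior propensities.
simulate_analytes <- function(truth, cfg) {
  z_alcohol <- as.numeric(scale(log(truth$post_gkg)))
  mean_retention <- vapply(seq_len(nrow(truth)), function(i) {
    mean(quinine_retention(c(0.25, 0.5, 0.75, 1),
                           truth$c50_mM[i], truth$slope_mM[i]))
  }, numeric(1))
  z_quinine <- as.numeric(scale(log(truth$post_gkg * mean_retention)))
  couplings <- default_analyte_couplings()
  base_conc <- setNames(rlnorm(length(ANALYTE_PANEL), log(10), 0.8),
                        ANALYTE_PANEL)
  grid <- tidyr::crossing(subject = truth$subject,
                          region = c("mPFC", "dPAG"),
                          analyte = ANALYTE_PANEL)
  grid$z <- 0
  for (j in seq_len(nrow(couplings))) {
    hit <- grid$region == couplings$region[j] &
      grid$analyte == couplings$analyte[j]
    z <- if (couplings$metric[j] == "alcohol") z_alcohol else z_quinine
    grid$z[hit] <- z[match(grid$subject[hit], truth$subject)]
  }
  grid$concentration <- base_conc[grid$analyte] *
    exp(cfg$analyte_coupling * grid$z +
          rnorm(nrow(grid), 0, cfg$analyte_noise_sdlog))
  grid$z <- NULL
  grid
}

#' Simulate a full synthetic cohort
#'
#' Generates a complete dataset with known ground truth: latent subjects,
#' the pre-binge epoch (3 alcohol-only + 4 quinine-adulterated sessions at
#' 0.25/0.5/0.75/1 mM), 14 days of two-bottle choice binge drinking (the
#' weekly cycle of four 2 h days, one 4 h day and two abstinence days,
#' repeated), the post-binge phenotyping epoch (same 3 + 4 structure), and
#' an optional analyte table with monotone couplings to the latent
#' propensities. Epochs listed in `cfg$event_epochs` carry full
#' timestamped event logs; the rest carry session summaries drawn from the
#' same latent model. One seed fully determines the dataset.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#' @param analytes Generate the analyte table (default TRUE).
#' @return A list of class `star_cohort`: `truth` (latent subjects),
#'   `records` (named list of [event_record()]s, possibly empty),
#'   `sessions` (session summary tibble across operant epochs),
#'   `two_bottle` (binge-epoch tibble), `analytes` (tibble or NULL),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1,
                            analytes = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_rng(seed, {
    truth <- purrr::map_dfr(seq_len(cfg$n_subjects), function(i) {
      simulate_subject(cfg, sprintf("m%02d", i))
    })

    schedule <- tibble::tibble(
      epoch = rep(c("pre_binge", "phenotyping"), each = 7),
      session_index = rep(1:7, 2),
      condition = rep(c(rep("alcohol_only", 3), rep("alcohol_quinine", 4)),
                      2),
      quinine_mM = rep(c(0, 0, 0, 0.25, 0.5, 0.75, 1), 2))

    records <- list()
    sessions <- vector("list", nrow(truth) * nrow(schedule))
    s <- 0L
    for (i in seq_len(nrow(truth))) {
      subj <- truth[i, ]
      for (j in seq_len(nrow(schedule))) {
        s <- s + 1L
        sch <- schedule[j, ]
        if (sch$epoch %in% cfg$event_epochs) {
          sim <- simulate_session(
            subj, cfg, epoch = sch$epoch, condition = sch$condition,
            quinine_mM = sch$quinine_mM, session_index = sch$session_index)
          records[[paste(subj$subject, sim$record$session_id, sep = "/")]] <-
            sim$record
          sessions[[s]] <- sim$summary
        } else {
          sessions[[s]] <- draw_session_summary(
            subj, cfg, sch$epoch, sch$condition, sch$quinine_mM,
            sch$session_index)
        }
      }
    }
    sessions <- dplyr::bind_rows(sessions)

    # binge epoch: two one-week cycles of 2,2,2,2,4,0,0 hours of access
    access_pattern <- rep(c(2, 2, 2, 2, 4, 0, 0), 2)
    two_bottle <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      purrr::map_dfr(seq_along(access_pattern), function(d) {
        out <- simulate_two_bottle(truth[i, ], cfg, access_pattern[d])
        out$day <- d
        out
      })
    })

    analyte_tbl <- if (analytes) simulate_analytes(truth, cfg) else NULL

    structure(
      list(truth = truth, records = records, sessions = sessions,
           two_bottle = two_bottle, analytes = analyte_tbl,
           config = cfg, seed = seed),
      class = "star_cohort")
  })
}

#' @export
print.star_cohort <- function(x, ...) {
  cat(sprintf(
    "<star_cohort> %d subjects (seed %s): %d session summaries, %d event logs\n",
    nrow(x$truth), format(x$seed), nrow(x$sessions), length(x$records)))
  print(table(x$truth$phenotype))
  invisible(x)
}
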