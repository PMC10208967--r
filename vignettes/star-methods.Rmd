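---
title: "Methods: phenotyping, stability analysis, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping, stability analysis, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starpheno)
```

This vignette documents the models and procedures implemented in
`starpheno`, the parameter choices that matter, and what the simulation-based
tests do and do not establish about real data.

## The task and its data

The framework analyzed here is operant alcohol self-administration in mice:
one-hour daily sessions in which responses on an active nose-poke are
reinforced under a fixed-ratio 10 (FR 10) schedule by a 10 s extension of a
retractable sipper containing 15% (v/v) ethanol, with individual licks
registered by a lickometer at millisecond resolution. Compulsive
(punishment-resistant) drinking is probed by adulterating the ethanol with
quinine at 0.25, 0.5, 0.75 and 1 mM over four sessions. An `event_record`
holds one session's timestamped stream (pokes, licks, sipper actuations);
`summarize_session()` reduces it to the per-session scalars — counts,
reinforcers, consumed volume and dose — used by every downstream stage.

Dose is expressed in g ethanol per kg body weight:

\[
\text{g/kg} = \frac{V_{mL} \times c_{v/v} \times \rho}{w_g / 1000},
\qquad \rho = 0.789\ \text{g/mL}.
\]

The ethanol density is not something a behavioral protocol states; we fix the
standard literature value and expose it as an argument. The weight used is
the same-day session weight (animals are weighed at the end of each daily
session).

## Phenotyping

For each subject two scores are computed, each as a percent of the sample
mean: the subject's mean g/kg over the alcohol-only sessions divided by the
mean of all subjects' means, × 100, and the same over the quinine sessions.
Classification: above-average punished intake (quinine score > 100) makes a
Compulsive Drinker regardless of the alcohol score; otherwise an alcohol
score > 100 makes a High Drinker, else a Low Drinker.

Three decisions were genuinely open and are fixed as follows:

* **Ties at exactly 100.** The classification rules use strict inequalities
  in both directions, which leaves a score of exactly 100.000 unassigned. We
  treat 100 as "not above average", so an exact tie resolves to the less
  severe label (quinine = 100 → not Compulsive; alcohol = 100 → Low). This
  is conservative — the more severe label requires being strictly above
  average — and matters in practice only for tiny or degenerate samples
  (e.g. two identical subjects), where it makes the tie behavior
  deterministic and testable.
* **Normalization denominator.** "Mean of all subjects" is ambiguous between
  the mean of subject-means and the grand mean of all session values; the
  two coincide exactly under the balanced 3 + 4 design and diverge only with
  missing sessions. We use the mean of subject-means, which keeps each
  subject's weight in the denominator equal regardless of how many sessions
  it contributed.
* **Missing sessions.** A subject's condition score uses the mean of its
  available sessions; a subject with zero sessions in a condition is dropped
  with a warning rather than imputed.

Sessions are mapped to the two conditions by their `condition` metadata, not
by position, so shortened designs (e.g. a three-session pharmacology series)
reuse the same machinery. `phenotype_cohort()` runs for any n ≥ 2 but warns
below n = 15, the recommended minimum sample size (see below).

## Sample-size stability

Because the normalization is re-estimated from the sample at hand, labels
are sample-relative, and their stability must be established empirically.
`mismatch_curve()` implements a permutated resampling analysis: for each
subsample size k (default 2 … N), it draws k subjects uniformly without
replacement, re-runs the phenotyping on the subsample alone, and compares
the subsample labels to the full-cohort labels, over (default) 100
independent iterations per size.

Two statistics can be formed: the per-subject mismatch probability (pooled
label disagreements / (k × iterations)) and the per-iteration probability
that at least one sampled subject changes label. The per-subject statistic
is the primary one — it is the empirical probability that *a subject's*
assignment changes — and the per-iteration statistic is reported alongside
(`any_mismatch_prob`). The Monte-Carlo standard error is the standard error
of the per-iteration mismatch fractions.

Numerical notes:

* The subsample classification uses the *same arithmetic* as the
  full-cohort path (`pct = 100 x / mean(x[S])`), so the k = N subsample
  reproduces the full-cohort labels bit-for-bit and `mismatch_prob(N) = 0`
  exactly — a structural identity the tests assert, not a tolerance.
* A root seed spawns one substream per subsample size, so a fixed seed
  yields a bit-identical curve and sizes could be evaluated independently.
* `exact_mismatch()` computes the same quantity by exhaustive enumeration of
  all C(N, k) subsets (bounded at 10^6 subsets). It exists as the
  brute-force oracle for validating the Monte-Carlo estimator on small
  cohorts and is tested against a three-subject cohort worked by hand.

`recommend_min_n()` returns the smallest evaluated k from which the
mismatch probability stays at or below a tolerance for every larger
evaluated size. "Highly stable" is not a quantified notion; the default
tolerance of 0.05 — at most a 5% chance that a subject's label would change
under re-sampling — is our choice and is exposed as an argument. On
simulated 41-subject cohorts with the default structure the recommendation
lands in the high single digits to low teens, consistent with a
minimum-sample recommendation of about 15 subjects with margin for real
data being noisier than the generator.

## Operant acquisition state machine

Acquisition sessions terminate at 100 licks or one hour, whichever comes
first, and proceed through phases: magazine training (advance after the cap
is reached), FR 1 with 30 s access, FR 1 with 10 s access (each advancing
after the cap on two consecutive days), and FR 5 discrimination (acquired
at ≥ 70% active-side responding plus the cap, two consecutive sessions).
Three consecutive failures in a phase revert the subject one phase; the
third revert event removes the subject. `evaluate_acquisition()` replays a
session sequence through these rules. Two under-specified corners are fixed
as: (1) consecutive-success windows reset when a revert occurs; (2) the
magazine phase has no predecessor, so three consecutive magazine failures
count as a revert event with the phase unchanged — persistent
non-performers are thereby removed rather than retained indefinitely. A
discrimination index is undefined (NA, not 0) when a session has zero
responses; such sessions count as failures.

## Event-stream summaries

* **Binning** (`binned_rate()`) uses half-open [lo, hi) bins — an event
  exactly on a boundary belongs to the later bin — except that an event
  exactly at session end falls in the last bin. This makes re-binning exact:
  10 s bins are sums of aligned 1 s bins.
* **Cumulative records** are defined at t = 0 with value 0 and extended flat
  to the session end so that records from equal-length sessions align.
* **Lick microstructure** partitions the lick train into bursts: maximal
  runs with consecutive interlick intervals ≤ a threshold. The default
  threshold of 0.5 s is a conventional choice for mouse licking (within-burst
  intervals run ~0.1–0.15 s); it is configurable because no single value is
  canonical.
* **Debouncing**: lickometer contact chatter can register spurious contacts;
  `read_event_log(debounce_s = 0.02)` collapses licks closer than 20 ms.
  It is off by default (and for simulated data, which has no chatter).

## The correlation screen

`correlate_analytes()` computes Spearman's rank correlation (midranks for
ties) between each analyte's concentration — per brain region — and the two
normalized behavior scores, with pairwise-complete observations and a
minimum of 5 pairs per cell. The normalized percent scores are the default
behavior metrics (raw g/kg can be passed as extra metric columns).
P-values use the exact permutation null when n ≤ 10 and no ties are
present, and the t approximation otherwise. No multiple-testing correction
is applied by default — significance stars mark unadjusted p-values, which
is the convention for this kind of exploratory screen — and a
Benjamini–Hochberg option is available. The test suite checks the
implementation against an independent rank-then-Pearson oracle and checks
the false-positive rate on null-coupled simulated analytes.

## The synthetic cohort generator

No public dataset of this design exists, so the package ships a generator
(`simulate_cohort()`) that produces cohorts with the statistical structure
the pipeline assumes, plus a ground-truth sidecar of latent traits. It is
first-class, tested code: every pipeline stage is validated against it.

The latent model, per subject:

* **Phenotype** drawn with probabilities 19/41, 5/41, 17/41
  (Low/High/Compulsive) — the composition of the reference 41-subject
  male cohort.
* **Pre-binge intake propensity**: lognormal, mean 1.8 g/kg per 1-h
  session, CV 12% — limited between-subject variance, common to all
  phenotypes, matching the observation that phenotypic differences are
  absent before binge experience.
* **Post-binge amplification**: the pre-binge propensity × 0.85 (Low) or
  × 1.8 (High and Compulsive, equal by design — these phenotypes do not
  differ in unpunished intake), with 15% between-subject CV. Values are
  chosen to put post-binge unpunished intake in the 1.5–3.5 g/kg per
  session range typical of C57BL/6J operant studies.
* **Quinine retention**: a logistic curve in concentration, normalized to 1
  at 0 mM, with midpoints 0.30 / 0.35 / 2.0 mM (Low / High / Compulsive)
  and slopes 0.18 / 0.18 / 0.6 mM. Only the ordering is constrained by the
  phenomenon being modeled — Compulsive retention dominates at every tested
  concentration (mean retention over the 0.25–1 mM series ≈ 0.93 vs
  ≈ 0.27–0.30) — and the specific curve shapes are our parameterization.
* **Session noise**: lognormal with 15% CV around the session's expected
  intake.

Event-level sessions are generated by a mechanistic process: active pokes
as a renewal process (exponential gaps at 0.35 Hz × a lognormal per-subject
vigor; Compulsive subjects respond ~25% more vigorously), every 10th
ratio-eligible poke extending the sipper for 10 s, burst-structured licking
(bursts of ~12 licks at ~8 Hz separated by sub-second pauses) during access
windows until the session's intake target is consumed, a 2 s post-reinforcer
pause, sparse inactive pokes, and per-lick volumes of 1.5 µL with 20% CV (a
mouse-typical lick volume; no canonical value exists). Pokes emitted during
an open access window are logged but not ratio-eligible — the protocol does
not state this either way, so it is a flagged, configurable choice.
Timestamps are rounded to 1 ms, emulating the 1 kHz hardware clock. The
two-bottle-choice binge epoch (two weekly cycles of four 2-h days, one 4-h
day, two abstinence days) draws intake linear in access time at 1.3 g/kg/h
with no phenotype effect — total binge intake does not differ by phenotype,
which is exactly why individual differences must be measured under operant
conditions.

Analyte tables couple a subset of (region, analyte) cells log-linearly to
the standardized latent propensities — monoamines and their metabolites to
unpunished intake in both regions, dPAG excitatory/inhibitory amino acids
(glutamate, GABA, glutamine, aspartate) to punished intake — so the screen
has recoverable signal; setting `analyte_coupling = 0` yields a null table
for calibration checks.

What the generator does *not* emulate: within-session satiation dynamics
beyond a simple rate drop, circadian structure, inter-day carryover,
acquisition-phase learning curves (acquisition sessions are simulated only
via the lick cap), quinine taste sampling at the first lick, and any
pharmacokinetics. Consequently, passing tests establish that the pipeline's
computations are correct and that its statistical behavior (recovery rates,
stability curves, screen calibration) is as designed *under this model* —
not that real cohorts will show the same recovery rates or stabilize at the
same sample size.

## Problem sizes and reproducibility

The validation suite works at sizes chosen to exercise each property well:
1,000 random cohorts (n = 2–100) for score conservation and rule
transcription; exhaustive-enumeration cross-checks at N = 4–6 with 10,000
Monte-Carlo iterations per size; one 41-subject cohort for the full
stability protocol (k = 2…41, 100 iterations); 100 simulated cohorts for
phenotype recovery (observed mean recovery ≈ 97%) and 100 regressions for
calibration-interval coverage. Cohorts used in bulk are simulated at the
summary level (the event-level and summary-level paths draw from the same
latent model); event-level invariants are checked on a full event-simulated
cohort. Every stochastic computation takes an explicit seed, and one root
seed determines a simulated dataset byte-for-byte.

## Known limitations

* The phenotyping is intentionally rigid (it is the cross-study comparison
  contract); no clustering or mixture-model alternative is provided.
* The stability analysis quantifies label churn under subsampling of the
  *observed* cohort; it is not a power analysis for group comparisons.
* The exact-enumeration oracle is limited to small cohorts by
  combinatorics.
* Raw proprietary operant-chamber formats are not parsed; the expected
  long-format CSV (`subject, session, time_s, kind`) is documented in
  `read_event_log()`, and converters are the user's responsibility.
* The screen's exact p-values require tie-free data; with ties it falls
  back to the t approximation, which is approximate at small n.
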