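#' Convert consumed volume to ethanol dose in g/kg
#'
#' The standard rodent drinking dose: grams of ethanol consumed per kilogram
#' of body weight. Volume is converted to ethanol mass using the solution
#' strength and the density of ethanol.
#'
#' @param consumed_volume_mL Consumed solution volume in milliliters (>= 0).
#' @param ethanol_vv Ethanol fraction of the solution, v/v (default 0.15,
#'   i.e. 15% ethanol in water).
#' @param weight_g Subject body weight in grams (> 0).
#' @param density_g_mL Density of ethanol in g/mL (default 0.789).
#'
#' @return Intake in g ethanol / kg body weight. Vectorized over all
#'   arguments.
#' @export
#' @examples
#' compute_intake_gkg(1.0, 0.15, 25)   # 4.734
compute_intake_gkg <- function(consumed_volume_mL, ethanol_vv = 0.15,
                               weight_g, density_g_mL = ETHANOL_DENSITY_G_PER_ML) {
  if (any(weight_g <= 0, na.rm = TRUE)) {
    abort("`weight_g` must be positive.", class = "starpheno_domain_error")
  }
  if (any(consumed_volume_mL < 0, na.rm = TRUE)) {
    abort("`consumed_volume_mL` must be non-negative.",
          class = "starpheno_domain_error")
  }
  if (any(ethanol_vv <= 0 | ethanol_vv >= 1, na.rm = TRUE)) {
    abort("`ethanol_vv` must be in (0, 1).", class = "starpheno_domain_error")
  }
  consumed_volume_mL * ethanol_vv * density_g_mL / (weight_g / 1000)
}

#' Fit the lick-count to intake calibration line
#'
#' Lick contacts on the sipper are highly correlated with volumetric intake,
#' so a per-rig ordinary least-squares line mapping session lick count to
#' g/kg intake gives a time-resolved consumption readout within sessions.
#'
#' @param licks Session lick counts (length >= 3, non-constant).
#' @param intake_gkg Matching volumetric g/kg intakes.
#'
#' @return An object of class `lick_calibration`: list with `slope`
#'   (g/kg per lick), `intercept` (g/kg), `r` (Pearson correlation of the
#'   pairs), `n_pairs`, and the underlying `fit` (an `lm` object, for
#'   confidence intervals).
#' @export
fit_lick_calibration <- function(licks, intake_gkg) {
  if (length(licks) != length(intake_gkg)) {
    abort("`licks` and `intake_gkg` must have equal length.",
          class = "starpheno_domain_error")
  }
  keep <- !(is.na(licks) | is.na(intake_gkg))
  licks <- licks[keep]; intake_gkg <- intake_gkg[keep]
  if (length(licks) < 3) {
    abort("Calibration requires at least 3 complete (licks, intake) pairs.",
          class = "starpheno_domain_error")
  }
  if (sd(licks) == 0) {
    abort("Calibration is degenerate: lick counts are constant.",
          class = "starpheno_degenerate_fit_error")
  }
  fit <- lm(intake_gkg ~ licks)
  structure(
    list(slope = unname(coef(fit)[["licks"]]),
         intercept = unname(coef(fit)[["(Intercept)"]]),
         r = if (sd(intake_gkg) == 0) NA_real_ else cor(licks, intake_gkg),
         n_pairs = length(licks),
         fit = fit),
    class = "lick_calibration")
}

#' @export
print.lick_calibration <- function(x, ...) {
  cat(sprintf(
    "<lick_calibration> intake = %.5g + %.5g * licks (g/kg), r = %.3f, n = %d\n",
    x$intercept, x$slope, x$r, x$n_pairs))
  invisible(x)
}

#' Predict g/kg intake from a lick count
#'
#' Applies a fitted [fit_lick_calibration()] line; predictions are clipped
#' at zero (a lick count cannot imply negative consumption).
#'
#' @param cal A `lick_calibration` object.
#' @param licks Lick count(s), >= 0.
#' @return Predicted intake in g/kg (vectorized, never negative).
#' @export
predict_intake_from_licks <- function(cal, licks) {
  stopifnot(inherits(cal, "lick_calibration"))
  if (any(licks < 0)) {
    abort("`licks` must be non-negative.", class = "starpheno_domain_error")
  }
  pmax(0, cal$slope * licks + cal$intercept)
}

#' Two-bottle choice alcohol preference
#'
#' Fraction of total fluid intake taken from the alcohol bottle during a
#' two-bottle choice session.
#'
#' @param alcohol_mL,water_mL Consumed volumes in mL (>= 0). Vectorized.
#' @return `alcohol / (alcohol + water)`, or `NA` where both volumes are
#'   zero (preference undefined).
#' @export
preference_ratio <- function(alcohol_mL, water_mL) {
  if (any(alcohol_mL < 0 | water_mL < 0, na.rm = TRUE)) {
    abort("Volumes must be non-negative.", class = "starpheno_domain_error")
  }
  total <- alcohol_mL + water_mL
  ifelse(total > 0, alcohol_mL / total, NA_real_)
}
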