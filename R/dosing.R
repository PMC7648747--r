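#' Gestational dose adjustment matching nonpregnant exposure
#'
#' Solves for the dose at a given gestational age that restores the
#' nonpregnant steady-state 24-h exposure (AUC24). Because the model is
#' linear in dose, the continuous matched dose is
#' `reference_dose * AUC24_nonpregnant / AUC24_pregnant(reference dose)`;
#' a confirmatory simulation at the continuous dose verifies the achieved
#' AUC ratio to within 0.1%. The continuous dose is then rounded to the
#' nearest total achievable from commercial tablet strengths.
#'
#' @param model A `pbpk_model` (any gestational age; its configuration is
#'   reused at `ga` and at 0).
#' @param ga Gestational age of interest, weeks.
#' @param reference_dose Nonpregnant reference dose, mg.
#' @param interval_h,n_doses Steady-state regimen.
#' @param max_tablets Tablet cap for rounding (see
#'   [round_to_strengths()]).
#' @return An object of class `dose_recommendation`: `ga`,
#'   `reference_dose`, `continuous_dose`, `rounded_dose`,
#'   `dose_multiplier`, `achieved_auc_ratio` (pregnant AUC at the rounded
#'   dose over nonpregnant AUC at the reference dose), and
#'   `confirmation_ratio` (same at the continuous dose; 1 to within 1e-3).
#' @export
required_dose <- function(model, ga, reference_dose = 100, interval_h = 24,
                          n_doses = 30, max_tablets = 2) {
  if (ga < 0 || ga > 42) stop("ga must be in [0, 42]", call. = FALSE)
  reg <- regimen(reference_dose, interval_h, n_doses)
  m0 <- pbpk_model(model$drug, model$physiology, model$gestation, ga = 0)
  mg <- pbpk_model(model$drug, model$physiology, model$gestation, ga = ga)
  auc0 <- nca(simulate_profile(m0, reg, washout_h = interval_h,
                               coarse_dt = 2))$auc24
  aucg <- nca(simulate_profile(mg, reg, washout_h = interval_h,
                               coarse_dt = 2))$auc24
  continuous <- reference_dose * auc0 / aucg

  confirm <- nca(simulate_profile(mg, regimen(continuous, interval_h, n_doses),
                                  washout_h = interval_h, coarse_dt = 2))$auc24
  confirmation_ratio <- confirm / auc0
  if (abs(confirmation_ratio - 1) > 1e-3) {
    stop(sprintf("dose-linearity confirmation failed (AUC ratio %.5f)",
                 confirmation_ratio), call. = FALSE)
  }
  rounded <- round_to_strengths(continuous, model$drug$tablet_strengths_mg,
                                max_tablets = max_tablets)
  achieved <- nca(simulate_profile(mg, regimen(rounded, interval_h, n_doses),
                                   washout_h = interval_h,
                                   coarse_dt = 2))$auc24 / auc0
  structure(list(ga = ga, reference_dose = reference_dose,
                 continuous_dose = continuous, rounded_dose = rounded,
                 dose_multiplier = continuous / reference_dose,
                 achieved_auc_ratio = achieved,
                 confirmation_ratio = confirmation_ratio),
            class = "dose_recommendation")
}

#' @export
print.dose_recommendation <- function(x, ...) {
  cat(sprintf("Dose recommendation at gestational age %g weeks\n", x$ga))
  cat(sprintf("  reference (nonpregnant) dose: %g mg\n", x$reference_dose))
  cat(sprintf("  AUC-matched continuous dose:  %.1f mg (%+.0f%%)\n",
              x$continuous_dose, 100 * (x$dose_multiplier - 1)))
  cat(sprintf("  rounded to tablet strengths:  %g mg (achieved AUC ratio %.3f)\n",
              x$rounded_dose, x$achieved_auc_ratio))
  invisible(x)
}

#' Round a dose to commercially achievable tablet totals
#'
#' Enumerates all totals composable from at most `max_tablets` tablets
#' (with repetition) of the available strengths and returns the total
#' nearest the continuous dose. Ties round down — the conservative choice
#' for fetal exposure.
#'
#' @param continuous Continuous dose, mg.
#' @param strengths Available tablet strengths, mg.
#' @param max_tablets Maximum tablets per administration.
#' @return Achievable dose, mg.
#' @export
round_to_strengths <- function(continuous, strengths, max_tablets = 2) {
  if (!length(strengths)) stop("strengths must be non-empty", call. = FALSE)
  totals <- 0
  for (k in seq_len(max_tablets)) {
    totals <- unique(c(totals, as.vector(outer(totals, strengths, `+`))))
  }
  totals <- sort(setdiff(totals, 0))
  err <- abs(totals - continuous)
  best <- totals[err == min(err)]
  min(best)  # tie -> lower dose
}
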