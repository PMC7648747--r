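#' In vitro intrinsic clearance of one recombinant CYP enzyme
#'
#' Linear-kinetics clearance from a recombinant-enzyme incubation: the
#' maximum reaction rate divided by the substrate concentration, corrected
#' for nonspecific binding in the incubation.
#'
#' @param vmax Maximum reaction rate, pmol/min/pmol CYP.
#' @param s Substrate concentration, uM.
#' @param fu_mic Fraction unbound in the microsomal incubation (default 1).
#' @return Intrinsic clearance in uL/min/pmol CYP: `(vmax / s) / fu_mic`.
#' @export
clint_recombinant <- function(vmax, s, fu_mic = 1) {
  if (any(s <= 0)) stop("substrate concentration must be > 0", call. = FALSE)
  if (any(vmax <= 0) || any(fu_mic <= 0)) {
    stop("vmax and fu_mic must be > 0", call. = FALSE)
  }
  (vmax / s) / fu_mic
}

#' Scale per-enzyme in vitro clearance to whole-liver in vivo clearance
#'
#' The IVIVE chain: recombinant-enzyme intrinsic clearance (uL/min/pmol) is
#' multiplied by an inter-system extrapolation factor (ISEF), hepatic
#' enzyme abundance (pmol/mg microsomal protein), microsomal protein per
#' gram of liver (MPPGL, mg/g) and liver mass (g), then converted to L/h.
#' Per-enzyme clearances are summed to the total in vivo hepatic intrinsic
#' clearance and expressed as fractional contributions (fm). An optional
#' scalar calibrates the absolute total without touching the fm shares.
#'
#' @param enzymes Named list over the five CYPs, each with `vmax`, `isef`,
#'   `abundance` (as in the drug config `cyp_kinetics` block).
#' @param mppgl Microsomal protein per gram liver, mg/g.
#' @param liver_mass Liver mass, g.
#' @param s Substrate concentration, uM.
#' @param fu_mic Fraction unbound in the incubation.
#' @param calibration_factor Scalar applied uniformly to all per-enzyme
#'   clearances (default 1).
#' @return A list of class `hepatic_clearance`: `per_enzyme` (named, L/h),
#'   `total` (L/h), `fm` (named fractions summing to 1).
#' @export
scale_to_liver <- function(enzymes, mppgl, liver_mass, s = 0.5, fu_mic = 1,
                           calibration_factor = 1) {
  missing <- setdiff(CYP_ENZYMES, names(enzymes))
  if (length(missing)) {
    stop("cyp_kinetics is missing enzyme(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per <- vapply(CYP_ENZYMES, function(e) {
    k <- enzymes[[e]]
    rec <- clint_recombinant(k$vmax, s, fu_mic)         # uL/min/pmol
    ul_min <- rec * k$isef * k$abundance * mppgl * liver_mass
    ul_min * 60 / 1e6 * calibration_factor              # -> L/h
  }, numeric(1))
  hepatic_clearance(per)
}

hepatic_clearance <- function(per_enzyme) {
  total <- sum(per_enzyme)
  structure(list(per_enzyme = per_enzyme, total = total,
                 fm = per_enzyme / total),
            class = "hepatic_clearance")
}

#' @export
print.hepatic_clearance <- function(x, ...) {
  cat("Hepatic intrinsic clearance (in vivo)\n")
  cat(sprintf("  total: %.1f L/h\n", x$total))
  for (e in names(x$per_enzyme)) {
    cat(sprintf("  %-8s %8.2f L/h  (fm %.1f%%)\n",
                e, x$per_enzyme[[e]], 100 * x$fm[[e]]))
  }
  invisible(x)
}

#' Hepatic intrinsic clearance from configuration
#'
#' Convenience wrapper running the full IVIVE chain on a drug parameter set
#' and physiology, including the drug's frozen calibration scalar.
#'
#' @param drug A [load_drug_params()] object.
#' @param physiology A [load_physiology()] object.
#' @param calibrated Apply the drug's `clint_calibration_factor`
#'   (default `TRUE`).
#' @return A `hepatic_clearance` object (nonpregnant baseline).
#' @export
hepatic_clearance_base <- function(drug, physiology, calibrated = TRUE) {
  scale_to_liver(drug$cyp_kinetics, physiology$mppgl, physiology$liver_mass,
                 s = drug$substrate_conc_uM, fu_mic = drug$fu_mic,
                 calibration_factor = if (calibrated) drug$clint_calibration_factor else 1)
}

#' Gestational hepatic intrinsic clearance
#'
#' Applies per-enzyme gestational activity multipliers to a baseline
#' clearance. Only CYP3A4 and CYP2D6 carry gestational equations; the other
#' enzymes keep multiplier 1. The total then satisfies
#' `total(ga)/total(0) = sum(fm_e * m_e(ga))`.
#'
#' @param base A nonpregnant `hepatic_clearance` object.
#' @param state A `gestational_state` (or a named multiplier vector).
#' @return A `hepatic_clearance` object at the state's gestational age.
#' @export
clint_at_ga <- function(base, state) {
  mult <- if (inherits(state, "gestational_state")) state$cyp_multipliers else state
  m <- setNames(rep(1, length(base$per_enzyme)), names(base$per_enzyme))
  m[names(mult)] <- mult
  hepatic_clearance(base$per_enzyme * m)
}
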