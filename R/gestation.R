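#' Evaluate one gestational scaling function
#'
#' @param entry One quantity from a [load_gestational_coefficients()] set:
#'   a list with `form = "polynomial"` (plus `coefficients`, increasing
#'   power order) or `form = "sigmoid"` (plus `amplitude`, `midpoint`,
#'   `width`; evaluated as `1 + amplitude * (S(ga) - S(0))`).
#' @param ga Gestational age in weeks (vectorized).
#' @return Numeric vector of the same length as `ga`.
#' @export
ga_eval <- function(entry, ga) {
  if (any(ga < 0)) stop("gestational age must be >= 0", call. = FALSE)
  if (entry$form == "polynomial") {
    co <- entry$coefficients
    out <- rep(co[length(co)], length(ga))
    for (k in rev(seq_len(length(co) - 1L))) out <- out * ga + co[k]
    out
  } else {
    s <- function(g) 1 / (1 + exp(-(g - entry$midpoint) / entry$width))
    1 + entry$amplitude * (s(ga) - s(0))
  }
}

#' Fraction unbound in plasma at a given albumin level
#'
#' Albumin-scaled binding model: the nonpregnant bound:unbound ratio
#' `(1 - fu0)/fu0` is assumed proportional to the albumin concentration,
#' giving `fu = fu0 / (fu0 + (1 - fu0) * albumin_ratio)` (algebraically
#' `1 / (1 + albumin_ratio * (1 - fu0)/fu0)`). The gestational fall in serum albumin
#' therefore raises the unbound fraction.
#'
#' @param fu0 Nonpregnant fraction unbound, in (0, 1).
#' @param albumin_ratio Albumin concentration relative to nonpregnancy,
#'   in (0, 1.2].
#' @return Fraction unbound; equals `fu0` when `albumin_ratio = 1` and is
#'   at least `fu0` whenever `albumin_ratio <= 1`.
#' @export
fu_at_ga <- function(fu0, albumin_ratio) {
  if (any(fu0 <= 0) || any(fu0 >= 1)) {
    stop("fu0 must be in (0, 1)", call. = FALSE)
  }
  if (any(albumin_ratio <= 0) || any(albumin_ratio > 1.2)) {
    stop("albumin_ratio must be in (0, 1.2]", call. = FALSE)
  }
  fu0 / (fu0 + (1 - fu0) * albumin_ratio)
}

#' Gestational-age snapshot of maternal physiology
#'
#' Evaluates every gestational scaling function at `ga` and routes the
#' pregnancy-gained mass: the lumped placental-fetal volume joins the
#' richly perfused compartment, expanded plasma volume stays in plasma, and
#' the remaining weight gain (predominantly maternal fat) joins the slowly
#' perfused compartment. Compartment blood flows keep their nonpregnant
#' fractions of the (increased) cardiac output, so flows always sum to
#' cardiac output. At `ga = 0` the returned state reproduces the
#' nonpregnant physiology exactly.
#'
#' @param physiology A [load_physiology()] object.
#' @param coeffs A [load_gestational_coefficients()] object.
#' @param ga Gestational age in weeks (scalar, 0 to 42).
#' @param fu0 Optional nonpregnant fraction unbound; when supplied the
#'   state carries the gestational `fu` via [fu_at_ga()].
#' @return A list of class `gestational_state`: `ga`, `body_weight` (kg),
#'   `cardiac_output` (L/h), `albumin_ratio`, `fu`, named `volumes` (L),
#'   named `flows` (L/h), `cyp_multipliers`, `placental_fetal_volume` (L).
#' @export
gestation_scale <- function(physiology, coeffs, ga, fu0 = NULL) {
  stopifnot(length(ga) == 1)
  if (ga < 0) stop("gestational age must be >= 0", call. = FALSE)
  if (ga > 42) stop("gestational age must be <= 42 weeks", call. = FALSE)

  bw0 <- physiology$body_weight0
  co0 <- physiology$cardiac_output0
  vf <- physiology$volume_fractions
  qf <- physiology$flow_fractions

  gain <- ga_eval(coeffs$body_weight_gain_kg, ga)
  pf <- ga_eval(coeffs$placental_fetal_volume_L, ga)
  pl_ratio <- ga_eval(coeffs$plasma_volume_ratio, ga)
  co_ratio <- ga_eval(coeffs$cardiac_output_ratio, ga)
  alb <- ga_eval(coeffs$albumin_ratio, ga)

  v_pl0 <- vf$plasma * bw0
  v_pl <- v_pl0 * pl_ratio
  # residual gain after placental-fetal and plasma expansion -> fat/other
  fat_gain <- max(gain - pf - (v_pl - v_pl0), 0)

  volumes <- c(
    plasma = v_pl,
    gut = vf$gut * bw0,
    liver = vf$liver * bw0,
    richly_perfused = vf$richly_perfused * bw0 + pf,
    slowly_perfused = vf$slowly_perfused * bw0 + fat_gain
  )
  co <- co0 * co_ratio
  flows <- setNames(
    unlist(qf[FLOW_COMPARTMENTS]) * co,
    FLOW_COMPARTMENTS
  )
  cyp <- c(CYP3A4 = ga_eval(coeffs$cyp3a4_multiplier, ga),
           CYP2B6 = 1, CYP2C9 = 1, CYP2C19 = 1,
           CYP2D6 = ga_eval(coeffs$cyp2d6_multiplier, ga))

  structure(list(
    ga = ga,
    body_weight = bw0 + gain,
    cardiac_output = co,
    albumin_ratio = alb,
    fu = if (is.null(fu0)) NA_real_ else fu_at_ga(fu0, alb),
    volumes = volumes,
    flows = flows,
    cyp_multipliers = cyp,
    placental_fetal_volume = pf
  ), class = "gestational_state")
}

#' Back-calculate pre-pregnancy body weight
#'
#' Inverts the gestational weight-gain function: subtracts the predicted
#' gain at `ga` from a measured current weight. Used when entering
#' per-subject verification data recorded during pregnancy.
#'
#' @param body_weight Current (pregnant) body weight, kg.
#' @param ga Gestational age in weeks.
#' @param coeffs A [load_gestational_coefficients()] object.
#' @return Pre-pregnancy body weight, kg.
#' @export
prepregnancy_weight <- function(body_weight, ga, coeffs) {
  body_weight - ga_eval(coeffs$body_weight_gain_kg, ga)
}
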