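#' Normalized local sensitivity coefficient
#'
#' Finite-difference elasticity of a model output with respect to an input
#' parameter: `SC = ((MO' - MO)/(IP' - IP)) * (IP/MO)`, where MO/MO' are
#' the baseline and perturbed outputs and IP/IP' the baseline and
#' perturbed inputs (conventionally `IP' = 1.1 * IP`).
#'
#' @param mo Baseline output value.
#' @param mo_prime Output after the input perturbation.
#' @param ip Baseline input value.
#' @param ip_prime Perturbed input value.
#' @return Dimensionless sensitivity coefficient.
#' @export
sensitivity_coefficient <- function(mo, mo_prime, ip, ip_prime) {
  if (any(ip_prime == ip)) stop("ip_prime must differ from ip", call. = FALSE)
  if (any(mo == 0)) stop("baseline output is zero", call. = FALSE)
  ((mo_prime - mo) / (ip_prime - ip)) * (ip / mo)
}

# parameters the local sensitivity analysis can perturb; each maps an id to
# a modification of the ODE parameter vector. body weight scales all
# compartment volumes, cardiac output all flows; molecular weight and pKa
# are carried in the drug file but enter no rate equation, so they act as
# inert controls.
SENSITIVITY_PARAMS <- c(
  "body_weight", "cardiac_output", "fu", "clint",
  "kp_gut", "kp_liver", "kp_richly_perfused", "kp_slowly_perfused",
  "v_plasma", "v_gut", "v_liver", "v_richly_perfused", "v_slowly_perfused",
  "q_gut", "q_hepatic_arterial", "q_richly_perfused", "q_slowly_perfused",
  "ka_max", "tau_a", "cl_bile", "k_empty", "molecular_weight", "pKa"
)

perturb_ode_params <- function(params, id, factor) {
  idx <- switch(id,
    body_weight = 1:5,
    cardiac_output = 6:9,
    fu = "fu", clint = "CLint",
    kp_gut = "Kp_gut", kp_liver = "Kp_liver",
    kp_richly_perfused = "Kp_richly", kp_slowly_perfused = "Kp_slowly",
    v_plasma = "V_plasma", v_gut = "V_gut", v_liver = "V_liver",
    v_richly_perfused = "V_richly", v_slowly_perfused = "V_slowly",
    q_gut = "Q_gut", q_hepatic_arterial = "Q_hepatic_arterial",
    q_richly_perfused = "Q_richly", q_slowly_perfused = "Q_slowly",
    ka_max = "ka_max", tau_a = "tau_a",
    cl_bile = "CL_bile", k_empty = "k_empty",
    molecular_weight = NULL, pKa = NULL,
    stop("unknown sensitivity parameter: ", id, call. = FALSE)
  )
  if (!is.null(idx)) params[idx] <- params[idx] * factor
  params
}

#' Local sensitivity analysis at steady state
#'
#' Perturbs each parameter by a fixed relative step (default +10%),
#' re-simulates the regimen, and reports the normalized sensitivity
#' coefficient of steady-state Cmax and AUC over the dosing interval.
#'
#' @param model A `pbpk_model`.
#' @param regimen A [regimen()].
#' @param parameters Parameter ids to perturb (see the default set).
#' @param rel_step Relative perturbation (0.1 = +10%).
#' @param outputs Outputs to track (`"cmax"`, `"auc24"`).
#' @param ... Passed to [simulate_profile()].
#' @return A data.frame of class `pbpk_sensitivity` with one row per
#'   parameter/output: `parameter`, `output`, `sc`, `mo`, `mo_prime`,
#'   `ip`, `ip_prime`, `pct_change`.
#' @export
sensitivity_analysis <- function(model, regimen = sertpbpk::regimen(200),
                                 parameters = SENSITIVITY_PARAMS,
                                 rel_step = 0.1,
                                 outputs = c("cmax", "auc24"), ...) {
  get_outputs <- function(params) {
    sim <- simulate_profile(params, regimen = regimen, washout_h = 24,
                            coarse_dt = 2, ...)
    r <- nca(sim)
    vapply(outputs, function(o) r[[o]], numeric(1))
  }
  base <- get_outputs(model$params)
  rows <- lapply(parameters, function(id) {
    pert <- get_outputs(perturb_ode_params(model$params, id, 1 + rel_step))
    data.frame(
      parameter = id, output = outputs,
      sc = vapply(seq_along(outputs), function(k) {
        sensitivity_coefficient(base[k], pert[k], 1, 1 + rel_step)
      }, numeric(1)),
      mo = unname(base), mo_prime = unname(pert),
      ip = 1, ip_prime = 1 + rel_step,
      pct_change = 100 * abs(unname(pert) - unname(base)) / unname(base),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pbpk_sensitivity", "data.frame")
  out
}

#' Screen for influential parameters
#'
#' Flags parameters whose +10% perturbation changes steady-state Cmax or
#' AUC by at least the threshold percentage.
#'
#' @param sens A [sensitivity_analysis()] result.
#' @param threshold_pct Reporting threshold in percent output change
#'   (default 0.5).
#' @return Character vector of flagged parameter ids.
#' @export
screen_sensitive <- function(sens, threshold_pct = 0.5) {
  flagged <- sens$parameter[sens$pct_change >= threshold_pct]
  unique(flagged)
}
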