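#' Oral dosing regimen
#'
#' @param dose_mg Dose per administration, mg.
#' @param interval_h Dosing interval, h.
#' @param n_doses Number of doses.
#' @param start_h Time of the first dose, h.
#' @return A list of class `regimen`.
#' @export
regimen <- function(dose_mg, interval_h = 24, n_doses = 30, start_h = 0) {
  if (dose_mg < 0) stop("dose must be >= 0", call. = FALSE)
  if (interval_h <= 0) stop("dosing interval must be > 0", call. = FALSE)
  if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
  structure(list(dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = n_doses, start_h = start_h),
            class = "regimen")
}

#' Assemble the gestational PBPK model
#'
#' Builds the full model object for a fixed gestational age: evaluates the
#' gestational physiology snapshot, the IVIVE hepatic clearance with its
#' gestational CYP activity multipliers, the calibrated tissue partition
#' set, and the combined ODE parameter vector used by the integrator.
#' Gestational age is held fixed within a simulation (a quasi-steady
#' snapshot; gestation moves on a scale of weeks, dosing on a scale of
#' hours).
#'
#' @param drug A [load_drug_params()] object (default: packaged
#'   sertraline).
#' @param physiology A [load_physiology()] object (default: packaged
#'   reference female).
#' @param gestation A [load_gestational_coefficients()] object.
#' @param ga Gestational age, weeks (0 = nonpregnant).
#' @return An object of class `pbpk_model` with elements `drug`,
#'   `physiology`, `gestation`, `ga`, `state` (gestational snapshot),
#'   `clearance0` / `clearance` (nonpregnant and gestational
#'   `hepatic_clearance`), `kp` (`partition_set`) and `params` (named ODE
#'   parameter vector).
#' @seealso [simulate.pbpk_model()], [nca()], [required_dose()]
#' @export
pbpk_model <- function(drug = load_drug_params(),
                       physiology = load_physiology(),
                       gestation = load_gestational_coefficients(),
                       ga = 0) {
  state <- gestation_scale(physiology, gestation, ga, fu0 = drug$fu0)
  cl0 <- hepatic_clearance_base(drug, physiology)
  cl <- clint_at_ga(cl0, state)
  kp <- partition_set(drug)
  m <- structure(list(drug = drug, physiology = physiology,
                      gestation = gestation, ga = ga, state = state,
                      clearance0 = cl0, clearance = cl, kp = kp),
                 class = "pbpk_model")
  m$params <- assemble_ode_params(m)
  m
}

# Fixed parameter order shared with src/pbpk.c.
ODE_PARAM_NAMES <- c(
  "V_plasma", "V_gut", "V_liver", "V_richly", "V_slowly",
  "Q_gut", "Q_hepatic_arterial", "Q_richly", "Q_slowly",
  "Kp_gut", "Kp_liver", "Kp_richly", "Kp_slowly",
  "fu", "CLint", "CL_bile", "k_empty", "ka_max", "tau_a",
  "t_dose", "ka_constant"
)

assemble_ode_params <- function(model) {
  st <- model$state
  kp <- model$kp$kp
  d <- model$drug
  setNames(c(
    st$volumes[["plasma"]], st$volumes[["gut"]], st$volumes[["liver"]],
    st$volumes[["richly_perfused"]], st$volumes[["slowly_perfused"]],
    st$flows[["gut"]], st$flows[["liver_arterial"]],
    st$flows[["richly_perfused"]], st$flows[["slowly_perfused"]],
    kp[["gut"]], kp[["liver"]], kp[["richly_perfused"]],
    kp[["slowly_perfused"]],
    st$fu, model$clearance$total, d$ehc$cl_bile, d$ehc$k_empty,
    d$absorption$ka_max, d$absorption$tau_a,
    0, 0
  ), ODE_PARAM_NAMES)
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("Gestational PBPK model: %s\n", x$drug$name))
  cat(sprintf("  gestational age: %g weeks%s\n", x$ga,
              if (x$ga == 0) " (nonpregnant)" else ""))
  cat(sprintf("  body weight %.1f kg, cardiac output %.0f L/h\n",
              x$state$body_weight, x$state$cardiac_output))
  cat(sprintf("  fu %.4f, CLint %.0f L/h  ->  CL/F %.1f L/h\n",
              x$state$fu, x$clearance$total,
              x$state$fu * x$clearance$total))
  invisible(x)
}

#' @export
summary.pbpk_model <- function(object, ...) {
  structure(list(model = object,
                 cl_f = object$state$fu * object$clearance$total,
                 fm = object$clearance0$fm,
                 clint_ratio = object$clearance$total / object$clearance0$total),
            class = "summary.pbpk_model")
}

#' @export
print.summary.pbpk_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  CLint gestational ratio: %.3f\n", x$clint_ratio))
  cat("  nonpregnant CYP contributions:\n")
  for (e in names(x$fm)) cat(sprintf("    %-8s %5.1f%%\n", e, 100 * x$fm[[e]]))
  cat("  compartment volumes (L):\n")
  v <- x$model$state$volumes
  for (n in names(v)) cat(sprintf("    %-16s %7.2f\n", n, v[[n]]))
  invisible(x)
}

#' @export
coef.pbpk_model <- function(object, ...) object$params

#' Simulate a dosing regimen with a PBPK model
#'
#' With `nsim = 1` (default) runs the deterministic model and returns a
#' [simulate_profile()] output; with `nsim > 1` runs a Monte Carlo
#' population simulation (see [monte_carlo()]).
#'
#' @param object A `pbpk_model`.
#' @param nsim Number of simulated subjects.
#' @param seed RNG seed (required for `nsim > 1`).
#' @param regimen A [regimen()]; default 200 mg daily for 30 days.
#' @param washout_h Post-last-dose observation window, h.
#' @param ... Passed to [simulate_profile()] or [monte_carlo()].
#' @return A `pbpk_sim` (deterministic) or `pbpk_mc` (population) object.
#' @export
simulate.pbpk_model <- function(object, nsim = 1, seed = NULL,
                                regimen = sertpbpk::regimen(200),
                                washout_h = 72, ...) {
  if (nsim > 1) {
    monte_carlo(object, regimen = regimen, n = nsim, seed = seed,
                washout_h = washout_h, ...)
  } else {
    if (!is.null(seed)) set.seed(seed)
    simulate_profile(object, regimen = regimen, washout_h = washout_h, ...)
  }
}

#' Predicted plasma concentrations at given times
#'
#' @param object A `pbpk_model`.
#' @param times Times (h) at which to report plasma concentration; default
#'   the simulation grid.
#' @param regimen A [regimen()].
#' @param ... Passed to [simulate_profile()].
#' @return data.frame with `time_h` and `conc_ug_per_L`.
#' @export
predict.pbpk_model <- function(object, times = NULL,
                               regimen = sertpbpk::regimen(200), ...) {
  sim <- simulate_profile(object, regimen = regimen, ...)
  if (is.null(times)) {
    data.frame(time_h = sim$time, conc_ug_per_L = sim$conc)
  } else {
    data.frame(time_h = times,
               conc_ug_per_L = approx(sim$time, sim$conc, xout = times,
                                      rule = 2)$y)
  }
}

#' @export
plot.pbpk_model <- function(x, regimen = sertpbpk::regimen(200),
                            final_interval = TRUE, ...) {
  sim <- simulate_profile(x, regimen = regimen)
  plot(sim, final_interval = final_interval, ...)
}
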