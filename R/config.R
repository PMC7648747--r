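#' @title Configuration loading and validation
#' @name config
#' @description Model constants live in three YAML files (drug, physiology,
#'   gestational coefficients), shipped under `inst/extdata`. Loaders
#'   validate every invariant and normalize units to the internal system
#'   (micrograms, liters, hours); masses declared in mg (doses, tablet
#'   strengths) are kept in mg at the interface and converted at the dosing
#'   boundary.
NULL

CYP_ENZYMES <- c("CYP3A4", "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6")
COMPARTMENTS <- c("plasma", "gut", "liver", "richly_perfused", "slowly_perfused")
FLOW_COMPARTMENTS <- c("gut", "liver_arterial", "richly_perfused", "slowly_perfused")
GESTATION_QUANTITIES <- c(
  body_weight_gain_kg = 0, plasma_volume_ratio = 1, cardiac_output_ratio = 1,
  placental_fetal_volume_L = 0, albumin_ratio = 1,
  cyp3a4_multiplier = 1, cyp2d6_multiplier = 1
)

# YAML scalars parse as integer when written without a decimal point;
# normalize so every stored parameter is double
cfg_numeric_tree <- function(x) {
  rapply(x, as.numeric, classes = "integer", how = "replace")
}

cfg_stop <- function(key, msg, got = NULL) {
  extra <- if (is.null(got)) "" else sprintf(" (got %s)", paste(format(got), collapse = ", "))
  stop(sprintf("config field '%s' %s%s", key, msg, extra), call. = FALSE)
}

cfg_need <- function(x, key) {
  val <- x[[key]]
  if (is.null(val)) cfg_stop(key, "is missing")
  val
}

cfg_num <- function(x, key, lower = -Inf, upper = Inf,
                    open_lower = FALSE, open_upper = FALSE, n = 1) {
  val <- cfg_need(x, key)
  if (!is.numeric(val) || (!is.na(n) && length(val) != n)) {
    cfg_stop(key, sprintf("must be numeric of length %s", n), val)
  }
  bad <- !is.finite(val) |
    (if (open_lower) val <= lower else val < lower) |
    (if (open_upper) val >= upper else val > upper)
  if (any(bad)) {
    cfg_stop(key, sprintf("must be in %s%s, %s%s",
                          if (open_lower) "(" else "[", format(lower),
                          format(upper), if (open_upper) ")" else "]"), val)
  }
  val
}

#' Load drug parameters
#'
#' Reads and validates a drug parameter file: physicochemical constants,
#' plasma/microsomal binding, tablet strengths, per-CYP in vitro kinetics
#' (Vmax in pmol/min/pmol CYP at the reported substrate concentration, an
#' inter-system extrapolation factor, and hepatic enzyme abundance in
#' pmol/mg microsomal protein), plus the frozen calibration constants
#' (intrinsic-clearance scalar, partition-coefficient adjustment factors,
#' absorption and enterohepatic parameters).
#'
#' @param path YAML file; defaults to the packaged sertraline set.
#' @return A validated list of class `drug_params`.
#' @export
load_drug_params <- function(path = sertpbpk_file("drug_sertraline.yaml")) {
  x <- cfg_numeric_tree(yaml::read_yaml(path))
  cfg_num(x, "molecular_weight", 0, open_lower = TRUE)
  cfg_num(x, "logP")
  cfg_num(x, "pKa")
  cfg_num(x, "fu0", 0, 1, open_lower = TRUE, open_upper = TRUE)
  cfg_num(x, "fu_mic", 0, 1, open_lower = TRUE)
  cfg_num(x, "blood_plasma_ratio", 0, open_lower = TRUE)
  ts <- cfg_num(x, "tablet_strengths_mg", 0, open_lower = TRUE, n = NA)
  if (is.unsorted(ts, strictly = TRUE)) {
    cfg_stop("tablet_strengths_mg", "must be strictly increasing", ts)
  }
  cfg_num(x, "substrate_conc_uM", 0, open_lower = TRUE)
  ck <- cfg_need(x, "cyp_kinetics")
  missing <- setdiff(CYP_ENZYMES, names(ck))
  if (length(missing)) {
    cfg_stop("cyp_kinetics", paste("is missing enzyme(s)",
                                   paste(missing, collapse = ", ")))
  }
  for (e in CYP_ENZYMES) {
    for (f in c("vmax", "isef", "abundance")) {
      cfg_num(ck[[e]], f, 0, open_lower = TRUE)
    }
  }
  cfg_num(x, "clint_calibration_factor", 0, open_lower = TRUE)
  for (f in c("ka_max", "tau_a")) cfg_num(x$absorption, f, 0, open_lower = TRUE)
  for (f in c("cl_bile", "k_empty")) cfg_num(x$ehc, f, 0)
  adj <- cfg_need(x, "kp_adjustment")
  for (f in setdiff(COMPARTMENTS, "plasma")) cfg_num(adj, f, 0, open_lower = TRUE)
  structure(x, class = "drug_params")
}

#' Load nonpregnant reference physiology
#'
#' Reference female anatomy: body weight, cardiac output, liver mass,
#' microsomal protein per gram of liver (MPPGL), and fractional compartment
#' volumes (of body weight, assuming unit tissue density) and blood flows
#' (of cardiac output). Flow fractions must sum to exactly 1 after lumping;
#' volume fractions to at most 1 (the compartments deliberately do not
#' cover whole-body mass).
#'
#' @param path YAML file; defaults to the packaged reference female set.
#' @return A validated list of class `physiology`.
#' @export
load_physiology <- function(path = sertpbpk_file("physiology_reference_female.yaml")) {
  x <- cfg_numeric_tree(yaml::read_yaml(path))
  cfg_num(x, "body_weight0", 0, open_lower = TRUE)
  cfg_num(x, "cardiac_output0", 0, open_lower = TRUE)
  cfg_num(x, "liver_mass", 0, open_lower = TRUE)
  cfg_num(x, "mppgl", 0, open_lower = TRUE)
  vf <- cfg_need(x, "volume_fractions")
  for (f in COMPARTMENTS) cfg_num(vf, f, 0, open_lower = TRUE)
  if (sum(unlist(vf[COMPARTMENTS])) > 1 + 1e-9) {
    cfg_stop("volume_fractions", "must sum to at most 1",
             sum(unlist(vf[COMPARTMENTS])))
  }
  qf <- cfg_need(x, "flow_fractions")
  for (f in FLOW_COMPARTMENTS) cfg_num(qf, f, 0, open_lower = TRUE)
  if (abs(sum(unlist(qf[FLOW_COMPARTMENTS])) - 1) > 1e-9) {
    cfg_stop("flow_fractions", "must sum to 1",
             sum(unlist(qf[FLOW_COMPARTMENTS])))
  }
  structure(x, class = "physiology")
}

#' Load gestational scaling coefficients
#'
#' Each gestational quantity is a parametric function of gestational age in
#' weeks: either `polynomial` (coefficients in increasing power order) or
#' `sigmoid` (`1 + amplitude * (S(ga) - S(0))` with
#' `S(g) = 1/(1 + exp(-(g - midpoint)/width))`). Every function must
#' evaluate to its nonpregnant reference (gain 0, ratio/multiplier 1) at
#' gestational age 0.
#'
#' @param path YAML file; defaults to the packaged coefficient set.
#' @return A validated list of class `gestational_coefficients`.
#' @export
load_gestational_coefficients <- function(path = sertpbpk_file("gestation_coefficients.yaml")) {
  x <- cfg_numeric_tree(yaml::read_yaml(path))
  for (q in names(GESTATION_QUANTITIES)) {
    entry <- cfg_need(x, q)
    form <- cfg_need(entry, "form")
    if (form == "polynomial") {
      cfg_num(entry, "coefficients", n = NA)
    } else if (form == "sigmoid") {
      cfg_num(entry, "amplitude")
      cfg_num(entry, "midpoint")
      cfg_num(entry, "width", 0, open_lower = TRUE)
    } else {
      cfg_stop(paste0(q, "$form"), "must be 'polynomial' or 'sigmoid'", form)
    }
    ref <- GESTATION_QUANTITIES[[q]]
    at0 <- ga_eval(entry, 0)
    if (abs(at0 - ref) > 1e-12) {
      cfg_stop(q, sprintf("must equal %s at gestational age 0", ref), at0)
    }
  }
  structure(x, class = "gestational_coefficients")
}

#' Load the full model configuration
#'
#' @param dir Directory holding `drug_sertraline.yaml`,
#'   `physiology_reference_female.yaml` and `gestation_coefficients.yaml`;
#'   defaults to the packaged configuration.
#' @return List with elements `drug`, `physiology`, `gestation`.
#' @export
load_config <- function(dir = system.file("extdata", package = "sertpbpk")) {
  list(
    drug = load_drug_params(file.path(dir, "drug_sertraline.yaml")),
    physiology = load_physiology(file.path(dir, "physiology_reference_female.yaml")),
    gestation = load_gestational_coefficients(file.path(dir, "gestation_coefficients.yaml"))
  )
}

#' Write a configuration object back to YAML
#'
#' Inverse of the loaders, used for round-tripping edited parameter sets.
#' Doubles are written with 15 significant digits so a write-then-load
#' cycle reproduces the parameter values.
#'
#' @param x A `drug_params`, `physiology` or `gestational_coefficients`
#'   object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  writeLines(yaml::as.yaml(unclass(x), precision = 15), path)
  invisible(path)
}

sertpbpk_file <- function(name) {
  f <- system.file("extdata", name, package = "sertpbpk")
  if (!nzchar(f)) stop("packaged config file not found: ", name, call. = FALSE)
  f
}
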