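#' Reference tissue composition table
#'
#' Fractional volumes of water, neutral lipid and phospholipid per tissue,
#' with plasma as the reference fluid, as used by the tissue-composition
#' partitioning method for lipophilic compounds. `lump` assigns each tissue
#' to a lumped model compartment (viscera to richly perfused; muscle, skin,
#' adipose and bone to slowly perfused) and `volume_L` gives the reference
#' female tissue volume used as the lumping weight.
#'
#' @return A data.frame with columns `tissue`, `f_water`,
#'   `f_neutral_lipid`, `f_phospholipid`, `lump`, `volume_L`.
#' @export
tissue_composition_table <- function() {
  data.frame(
    tissue = c("plasma", "gut", "liver", "brain", "heart", "kidney",
               "muscle", "skin", "adipose", "bone"),
    f_water = c(0.945, 0.718, 0.745, 0.770, 0.779, 0.783,
                0.760, 0.718, 0.180, 0.439),
    f_neutral_lipid = c(0.0035, 0.0487, 0.0348, 0.0510, 0.0115, 0.0207,
                        0.0220, 0.0284, 0.7900, 0.0740),
    f_phospholipid = c(0.00225, 0.0163, 0.0252, 0.0565, 0.0166, 0.0162,
                       0.0072, 0.0111, 0.0020, 0.0011),
    lump = c(NA, "gut", "liver", "richly_perfused", "richly_perfused",
             "richly_perfused", "slowly_perfused", "slowly_perfused",
             "slowly_perfused", "slowly_perfused"),
    volume_L = c(NA, 1.0, 1.4, 1.30, 0.25, 0.275,
                 17.5, 2.3, 22.5, 7.8),
    stringsAsFactors = FALSE
  )
}

# tissue binding correction: tissue interstitial binding proteins assumed at
# half the plasma concentration for non-adipose tissue; adipose unbound.
fu_tissue <- function(fu_p, tissue) {
  if (tissue == "adipose") 1 else 1 / (1 + 0.5 * (1 - fu_p) / fu_p)
}

#' Tissue:plasma partition coefficient by tissue composition
#'
#' Lipophilic-compound form of the tissue-composition method: with
#' `P = 10^logP`, the partition coefficient is the ratio of
#' `P * (f_nl + 0.3 f_ph) + (f_w + 0.7 f_ph)` in tissue over plasma,
#' multiplied by the binding correction `fu_p / fu_t`. For adipose the
#' tissue is treated as binding-protein free (`fu_t = 1`); for other
#' tissues the bound fraction scales with an assumed half-plasma
#' protein content. Ionization is ignored (logP, not logD): with a basic
#' pKa well above plasma pH the neutral-species approximation biases all
#' tissues alike and is absorbed by the calibrated adjustment factors.
#'
#' @param logP Octanol:water log partition coefficient.
#' @param fu0 Fraction unbound in plasma.
#' @param comp Tissue composition table ([tissue_composition_table()]
#'   layout); must contain `tissue` and a `"plasma"` row.
#' @param tissue Tissue name to evaluate.
#' @param fu_t Optional override of the tissue unbound fraction; by default
#'   it follows the convention above.
#' @return Dimensionless Kp (tissue:plasma, total concentrations).
#' @export
kp_poulin_haddad <- function(logP, fu0, comp = tissue_composition_table(),
                             tissue, fu_t = NULL) {
  row <- comp[comp$tissue == tissue, ]
  pl <- comp[comp$tissue == "plasma", ]
  if (nrow(row) != 1) stop("unknown tissue: ", tissue, call. = FALSE)
  p <- 10^logP
  lipid_term <- function(r) {
    p * (r$f_neutral_lipid + 0.3 * r$f_phospholipid) +
      (r$f_water + 0.7 * r$f_phospholipid)
  }
  if (is.null(fu_t)) fu_t <- fu_tissue(fu0, tissue)
  (lipid_term(row) / lipid_term(pl)) * fu0 / fu_t
}

#' Partition coefficients for the lumped model compartments
#'
#' Evaluates [kp_poulin_haddad()] for every tissue in the composition
#' table and aggregates member tissues into the model's lumped
#' compartments as volume-weighted means.
#'
#' @param logP,fu0 As in [kp_poulin_haddad()].
#' @param comp Tissue composition table.
#' @return Named vector of raw Kp over `gut`, `liver`, `richly_perfused`,
#'   `slowly_perfused`.
#' @export
kp_compartments <- function(logP, fu0, comp = tissue_composition_table()) {
  tissues <- comp[!is.na(comp$lump), ]
  kps <- vapply(tissues$tissue, function(tt) {
    kp_poulin_haddad(logP, fu0, comp, tt)
  }, numeric(1))
  vapply(setdiff(COMPARTMENTS, "plasma"), function(cp) {
    idx <- tissues$lump == cp
    sum(kps[idx] * tissues$volume_L[idx]) / sum(tissues$volume_L[idx])
  }, numeric(1))
}

#' Apply calibration adjustment factors to a partition set
#'
#' Element-wise product of raw partition coefficients with per-compartment
#' adjustment factors. The factors are fitted once against the nonpregnancy
#' calibration profile and then frozen as model constants.
#'
#' @param kp_raw Named Kp vector (or `partition_set`).
#' @param factors Named per-compartment positive scalars; compartments not
#'   named keep factor 1.
#' @return A list of class `partition_set` with `kp` (adjusted), `raw`,
#'   and `adjustment`.
#' @export
apply_adjustment <- function(kp_raw, factors) {
  if (inherits(kp_raw, "partition_set")) kp_raw <- kp_raw$raw
  f <- setNames(rep(1, length(kp_raw)), names(kp_raw))
  if (length(factors)) {
    factors <- unlist(factors)
    if (any(factors <= 0)) stop("adjustment factors must be > 0", call. = FALSE)
    f[names(factors)] <- factors
  }
  structure(list(kp = kp_raw * f, raw = kp_raw, adjustment = f),
            class = "partition_set")
}

#' Drug partition set (raw prediction plus frozen calibration)
#'
#' @param drug A [load_drug_params()] object.
#' @param comp Tissue composition table.
#' @return A `partition_set` with the drug's calibrated adjustment factors
#'   applied.
#' @export
partition_set <- function(drug, comp = tissue_composition_table()) {
  raw <- kp_compartments(drug$logP, drug$fu0, comp)
  apply_adjustment(raw, drug$kp_adjustment)
}
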