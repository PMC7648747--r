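#' Average fold error (bias)
#'
#' Geometric-mean fold error of predicted against observed values,
#' `AFE = 10^(mean(log10(predicted/observed)))`. Values below 1 indicate a
#' bias toward underprediction, above 1 toward overprediction.
#'
#' @param predicted,observed Positive numeric vectors of equal length.
#' @return Dimensionless AFE.
#' @export
afe <- function(predicted, observed) {
  check_pairs(predicted, observed)
  10^mean(log10(predicted / observed))
}

#' Absolute average fold error (precision)
#'
#' `AAFE = 10^(mean(|log10(predicted/observed)|))`; always at least 1,
#' and at least `max(AFE, 1/AFE)`.
#'
#' @inheritParams afe
#' @return Dimensionless AAFE (>= 1).
#' @export
aafe <- function(predicted, observed) {
  check_pairs(predicted, observed)
  10^mean(abs(log10(predicted / observed)))
}

#' Twofold-error flags
#'
#' Flags each predicted/observed pair whose ratio lies within the
#' inclusive interval \[0.5, 2\], and reports the flagged fraction.
#'
#' @inheritParams afe
#' @return List with `within` (logical per pair) and `fraction`.
#' @export
twofold_flags <- function(predicted, observed) {
  check_pairs(predicted, observed)
  ratio <- predicted / observed
  within <- ratio >= 0.5 & ratio <= 2
  list(within = within, fraction = mean(within))
}

check_pairs <- function(predicted, observed) {
  if (length(predicted) < 1 || length(predicted) != length(observed)) {
    stop("predicted and observed must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("predicted and observed values must be > 0 (log metrics)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarize predictive performance over predicted/observed pairs
#'
#' @inheritParams afe
#' @return An object of class `eval_summary`: `afe`, `aafe`,
#'   `twofold_fraction`, `n`.
#' @export
eval_summary <- function(predicted, observed) {
  structure(list(afe = afe(predicted, observed),
                 aafe = aafe(predicted, observed),
                 twofold_fraction = twofold_flags(predicted, observed)$fraction,
                 n = length(predicted)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("AFE %.2f, AAFE %.2f, %d/%d within twofold\n",
              x$afe, x$aafe, round(x$twofold_fraction * x$n), x$n))
  invisible(x)
}

#' Evaluate model predictions against an observed summary dataset
#'
#' For each subject, rebuilds the model at the subject's gestational age
#' with the pre-pregnancy body weight back-calculated from the recorded
#' (pregnant) weight via the gestational weight-gain function, simulates
#' the subject's reported regimen to steady state, and compares predicted
#' against observed Cmax and AUC24.
#'
#' @param observed data.frame with columns `subject`, `dose_mg`,
#'   `ga_weeks`, `body_weight_kg` (current weight), `cmax`, `auc24`, and
#'   optionally `trimester` and `exclude` (logical outlier flag honoured
#'   only when `apply_exclusions = TRUE`).
#' @param drug,physiology,gestation Model configuration objects.
#' @param n_doses Doses to steady state.
#' @param apply_exclusions Drop rows flagged `exclude` (default FALSE; the
#'   flag is caller-controlled, never automatic).
#' @return List with `pairs` (long data.frame: subject, metric, predicted,
#'   observed, within twofold) and `summaries` (one `eval_summary` per
#'   metric).
#' @export
evaluate_observed <- function(observed,
                              drug = load_drug_params(),
                              physiology = load_physiology(),
                              gestation = load_gestational_coefficients(),
                              n_doses = 30, apply_exclusions = FALSE) {
  need <- c("subject", "dose_mg", "ga_weeks", "body_weight_kg", "cmax", "auc24")
  missing <- setdiff(need, names(observed))
  if (length(missing)) {
    stop("observed data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (apply_exclusions && "exclude" %in% names(observed)) {
    observed <- observed[!observed$exclude, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(observed)), function(i) {
    o <- observed[i, ]
    ph <- physiology
    ph$body_weight0 <- prepregnancy_weight(o$body_weight_kg, o$ga_weeks,
                                           gestation)
    m <- pbpk_model(drug, ph, gestation, ga = o$ga_weeks)
    sim <- simulate_profile(m, regimen = regimen(o$dose_mg, 24, n_doses),
                            washout_h = 24, coarse_dt = 2)
    r <- nca(sim)
    data.frame(subject = rep(o$subject, 2),
               ga_weeks = rep(o$ga_weeks, 2),
               metric = c("cmax", "auc24"),
               predicted = c(r$cmax, r$auc24),
               observed = c(o$cmax, o$auc24),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pairs$within_twofold <- twofold_flags(pairs$predicted, pairs$observed)$within
  summaries <- lapply(split(pairs, pairs$metric), function(d) {
    eval_summary(d$predicted, d$observed)
  })
  list(pairs = pairs, summaries = summaries)
}
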