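#' Synthetic calibration-style dataset
#'
#' Emulates the structure of a steady-state calibration study (daily oral
#' tablets to steady state, serial sampling after the last dose): the true
#' model curve is sampled on a study-like schedule over the final dosing
#' interval plus washout, and multiplicative lognormal residual error with
#' the given coefficient of variation is applied per subject and time
#' point. With `noise_cv = 0` every point lies exactly on the model curve.
#'
#' @param model A `pbpk_model` (the generating truth).
#' @param regimen A [regimen()]; default 200 mg daily for 30 days.
#' @param n_subjects Number of synthetic subjects.
#' @param noise_cv Residual coefficient of variation (>= 0).
#' @param seed RNG seed; seeded runs are reproducible.
#' @param sample_times_h Sampling schedule relative to the last dose, h.
#' @return An object of class `observed_dataset`: data.frame with columns
#'   `subject`, `time_h`, `conc_ug_per_L`; attributes carry the seed,
#'   noise model and regimen.
#' @export
make_calibration_like <- function(model, regimen = sertpbpk::regimen(200),
                                  n_subjects = 11, noise_cv = 0.2, seed = 1,
                                  sample_times_h = c(seq(0, 24, by = 2),
                                                     seq(28, 96, by = 4))) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed)
  sim <- simulate_profile(model, regimen = regimen,
                          washout_h = max(sample_times_h))
  truth <- approx(sim$time - sim$t_last_dose, sim$conc,
                  xout = sample_times_h, rule = 2)$y
  rows <- lapply(seq_len(n_subjects), function(s) {
    eps <- mult_noise(length(truth), noise_cv)
    data.frame(subject = s, time_h = sample_times_h,
               conc_ug_per_L = truth * eps)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("observed_dataset", "data.frame"),
            seed = seed, noise_cv = noise_cv, regimen = regimen,
            truth = data.frame(time_h = sample_times_h,
                               conc_ug_per_L = truth))
}

mult_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, -sdlog^2 / 2, sdlog)  # mean 1
}

#' Synthetic pregnancy verification-style dataset
#'
#' Emulates the structure of a sparse pregnancy PK study: subjects on
#' various daily doses, with per-subject steady-state Cmax/AUC24
#' summaries at a second-trimester visit and (for a subset) a
#' third-trimester visit, plus lognormal between-subject body weights and
#' multiplicative residual noise on the summaries.
#'
#' @param model A `pbpk_model` built at gestational age 0 (the generating
#'   configuration; per-visit models are built at each subject's visit
#'   age).
#' @param n_trimester2,n_trimester3 Subjects observed at each visit
#'   (third-trimester subjects are a subset of the second-trimester ones).
#' @param doses_mg Pool of daily doses sampled per subject.
#' @param ga_trimester2,ga_trimester3 Visit windows, weeks.
#' @param noise_cv Residual CV on the summaries.
#' @param bw_cv Between-subject CV on pre-pregnancy body weight.
#' @param seed RNG seed.
#' @return An `observed_dataset` data.frame with columns `subject`,
#'   `trimester`, `dose_mg`, `ga_weeks`, `body_weight_kg` (current,
#'   pregnant weight), `cmax`, `auc24`.
#' @export
make_verification_like <- function(model, n_trimester2 = 8, n_trimester3 = 6,
                                   doses_mg = c(25, 50, 100, 150, 200),
                                   ga_trimester2 = c(22, 26),
                                   ga_trimester3 = c(30, 34),
                                   noise_cv = 0.3, bw_cv = 0.15, seed = 1) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  set.seed(seed)
  bw0 <- model$physiology$body_weight0 *
    mult_noise(n_trimester2, bw_cv)
  dose <- sample(doses_mg, n_trimester2, replace = TRUE)
  ga2 <- runif(n_trimester2, ga_trimester2[1], ga_trimester2[2])
  ga3 <- runif(n_trimester3, ga_trimester3[1], ga_trimester3[2])

  one_visit <- function(s, ga, trimester) {
    ph <- model$physiology
    ph$body_weight0 <- bw0[s]
    m <- pbpk_model(model$drug, ph, model$gestation, ga = ga)
    sim <- simulate_profile(m, regimen = regimen(dose[s], 24, 30),
                            washout_h = 24, coarse_dt = 2)
    r <- nca(sim)
    eps <- mult_noise(2, noise_cv)
    data.frame(subject = s, trimester = trimester, dose_mg = dose[s],
               ga_weeks = ga,
               body_weight_kg = bw0[s] +
                 ga_eval(model$gestation$body_weight_gain_kg, ga),
               cmax = r$cmax * eps[1], auc24 = r$auc24 * eps[2])
  }
  rows <- c(lapply(seq_len(n_trimester2), function(s) one_visit(s, ga2[s], 2L)),
            lapply(seq_len(n_trimester3), function(s) one_visit(s, ga3[s], 3L)))
  out <- do.call(rbind, rows)
  structure(out, class = c("observed_dataset", "data.frame"),
            seed = seed, noise_cv = noise_cv)
}

#' Write / read an observed dataset as CSV
#'
#' Plain-CSV interchange with the documented fixed column layouts
#' (concentration-time: `subject`, `time_h`, `conc_ug_per_L`; summaries
#' add `trimester`, `dose_mg`, `ga_weeks`, `body_weight_kg`, `cmax`,
#' `auc24`).
#'
#' @param x An `observed_dataset` (or plain data.frame).
#' @param path CSV file path.
#' @return `path` invisibly; `read_observed()` returns the data.frame.
#' @export
write_observed <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observed
#' @export
read_observed <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  structure(out, class = c("observed_dataset", "data.frame"))
}
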