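#' Truncated sampling distribution for one model parameter
#'
#' Population variability is described per parameter by a normal or
#' lognormal distribution around the model value with a coefficient of
#' variation, truncated at the family's own 2.5th and 97.5th percentiles
#' so that sampled values stay biologically plausible.
#'
#' @param id Parameter identifier.
#' @param family `"lognormal"` or `"normal"`.
#' @param mean Arithmetic mean (the model's deterministic value).
#' @param cv Coefficient of variation (fraction, >= 0; 0 collapses the
#'   distribution onto the mean).
#' @return A list of class `distribution_spec` with truncation bounds
#'   `lower`/`upper`.
#' @export
distribution_spec <- function(id, family = c("lognormal", "normal"),
                              mean, cv) {
  family <- match.arg(family)
  if (cv < 0) stop("cv must be >= 0 for '", id, "'", call. = FALSE)
  if (mean <= 0) stop("mean must be > 0 for '", id, "'", call. = FALSE)
  if (cv == 0) {
    lower <- upper <- mean
  } else if (family == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mean) - sdlog^2 / 2
    b <- qlnorm(c(0.025, 0.975), meanlog, sdlog)
    lower <- b[1]; upper <- b[2]
  } else {
    b <- qnorm(c(0.025, 0.975), mean, cv * mean)
    lower <- b[1]; upper <- b[2]
  }
  if (!(lower < mean && mean < upper) && cv > 0) {
    stop("infeasible truncation bounds for '", id, "'", call. = FALSE)
  }
  structure(list(id = id, family = family, mean = mean, cv = cv,
                 lower = lower, upper = upper),
            class = "distribution_spec")
}

#' Default population distribution set for a model
#'
#' Drug-specific parameters (partition coefficients, absorption and
#' elimination constants, fraction unbound) are lognormal; fractional
#' tissue volumes and blood flows are normal; body weight and cardiac
#' output are lognormal. Default coefficients of variation are 20% for
#' partition coefficients and 30% for physiological, absorption and
#' elimination parameters.
#'
#' @param model A `pbpk_model`.
#' @param cv_kp CV for partition coefficients.
#' @param cv_phys CV for physiological parameters.
#' @param cv_drug CV for absorption/elimination/binding parameters.
#' @return Named list of [distribution_spec()]s.
#' @export
default_distribution_specs <- function(model, cv_kp = 0.2, cv_phys = 0.3,
                                       cv_drug = 0.3) {
  ph <- model$physiology
  sp <- list(
    distribution_spec("body_weight", "lognormal", ph$body_weight0, cv_phys),
    distribution_spec("cardiac_output", "lognormal", ph$cardiac_output0, cv_phys)
  )
  for (cp in COMPARTMENTS) {
    sp <- c(sp, list(distribution_spec(paste0("v_frac_", cp), "normal",
                                       ph$volume_fractions[[cp]], cv_phys)))
  }
  for (cp in FLOW_COMPARTMENTS) {
    sp <- c(sp, list(distribution_spec(paste0("q_frac_", cp), "normal",
                                       ph$flow_fractions[[cp]], cv_phys)))
  }
  for (cp in setdiff(COMPARTMENTS, "plasma")) {
    sp <- c(sp, list(distribution_spec(paste0("kp_", cp), "lognormal",
                                       model$kp$kp[[cp]], cv_kp)))
  }
  sp <- c(sp, list(
    distribution_spec("fu0", "lognormal", model$drug$fu0, cv_drug),
    distribution_spec("clint0", "lognormal", model$clearance0$total, cv_drug),
    distribution_spec("ka_max", "lognormal", model$drug$absorption$ka_max, cv_drug),
    distribution_spec("tau_a", "lognormal", model$drug$absorption$tau_a, cv_drug),
    distribution_spec("cl_bile", "lognormal", model$drug$ehc$cl_bile, cv_drug),
    distribution_spec("k_empty", "lognormal", model$drug$ehc$k_empty, cv_drug)
  ))
  setNames(sp, vapply(sp, `[[`, "", "id"))
}

draw_truncated <- function(spec, n) {
  if (spec$cv == 0) return(rep(spec$mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    x <- if (spec$family == "lognormal") {
      sdlog <- sqrt(log(1 + spec$cv^2))
      rlnorm(m, log(spec$mean) - sdlog^2 / 2, sdlog)
    } else {
      rnorm(m, spec$mean, spec$cv * spec$mean)
    }
    # rejection (not clipping): keeps the distribution shape inside bounds
    out <- c(out, x[x >= spec$lower & x <= spec$upper])
  }
  out[seq_len(n)]
}

#' Sample population parameter sets
#'
#' Draws `n` parameter sets from truncated distributions by rejection
#' sampling, then renormalizes each draw's fractional blood flows to sum
#' exactly to 1 and fractional tissue volumes to the reference total
#' volume fraction, preserving whole-body mass balance.
#'
#' @param specs A list of [distribution_spec()]s (see
#'   [default_distribution_specs()]).
#' @param n Number of parameter sets.
#' @param seed RNG seed.
#' @return A data.frame with one row per set, one column per parameter.
#' @export
sample_parameters <- function(specs, n, seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  draws <- as.data.frame(lapply(specs, draw_truncated, n = n))
  names(draws) <- names(specs)

  vcols <- grep("^v_frac_", names(draws), value = TRUE)
  if (length(vcols)) {
    target <- sum(vapply(specs[vcols], `[[`, 0, "mean"))
    draws[vcols] <- draws[vcols] * (target / rowSums(draws[vcols]))
  }
  qcols <- grep("^q_frac_", names(draws), value = TRUE)
  if (length(qcols)) {
    draws[qcols] <- draws[qcols] / rowSums(draws[qcols])
  }
  draws
}

# Build an ODE parameter vector for one sampled row. Gestational increments
# (placental-fetal volume, fat gain, plasma expansion, CYP multipliers, fu
# scaling) are identical for every subject: the dynamic pregnancy-related
# trajectories are treated as uncertainty-free relative changes.
ode_params_for_draw <- function(model, row) {
  st <- model$state
  ph <- model$physiology
  p <- model$params
  bw <- row[["body_weight"]]
  co <- row[["cardiac_output"]]
  # gestational absolute increments on top of the nonpregnant baseline
  inc <- st$volumes - unlist(ph$volume_fractions[COMPARTMENTS]) * ph$body_weight0
  vols <- c(row[["v_frac_plasma"]], row[["v_frac_gut"]], row[["v_frac_liver"]],
            row[["v_frac_richly_perfused"]], row[["v_frac_slowly_perfused"]]) *
    bw + unname(inc)
  co_ratio <- st$cardiac_output / ph$cardiac_output0
  flows <- c(row[["q_frac_gut"]], row[["q_frac_liver_arterial"]],
             row[["q_frac_richly_perfused"]], row[["q_frac_slowly_perfused"]]) *
    co * co_ratio
  clint_ratio <- model$clearance$total / model$clearance0$total
  p[1:5] <- vols
  p[6:9] <- flows
  p[10:13] <- c(row[["kp_gut"]], row[["kp_liver"]],
                row[["kp_richly_perfused"]], row[["kp_slowly_perfused"]])
  p[["fu"]] <- fu_at_ga(min(row[["fu0"]], 0.999), st$albumin_ratio)
  p[["CLint"]] <- row[["clint0"]] * clint_ratio
  p[["ka_max"]] <- row[["ka_max"]]
  p[["tau_a"]] <- row[["tau_a"]]
  p[["CL_bile"]] <- row[["cl_bile"]]
  p[["k_empty"]] <- row[["k_empty"]]
  p
}

#' Monte Carlo population simulation
#'
#' Repeats the regimen simulation over sampled parameter sets, reporting
#' pointwise 2.5th/50th/97.5th percentile plasma concentrations (the 95%
#' prediction interval), per-iteration NCA results, and the NCA of the
#' pointwise-median curve. Failed integrations are resampled (at most 5%
#' of `n`).
#'
#' @param model A `pbpk_model`.
#' @param regimen A [regimen()].
#' @param n Number of iterations (>= 100 for percentile bands).
#' @param seed RNG seed; identical seeds give identical output.
#' @param specs Distribution set; defaults to
#'   [default_distribution_specs()].
#' @param washout_h Post-last-dose observation, h.
#' @param coarse_dt Output step during early intervals, h.
#' @param ... Passed to [simulate_profile()].
#' @return An object of class `pbpk_mc`: `time`, `bands` (matrix with
#'   columns `p2.5`, `p50`, `p97.5`), `nca` (per-iteration data.frame),
#'   `median_nca` (NCA of the median curve), `n`, `seed`, `n_failed`.
#' @export
monte_carlo <- function(model, regimen = sertpbpk::regimen(200), n = 1000,
                        seed = 1, specs = default_distribution_specs(model),
                        washout_h = 72, coarse_dt = 3, ...) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  draws <- sample_parameters(specs, n, seed)
  extra <- sample_parameters(specs, max(16L, ceiling(0.05 * n)),
                             seed + 104729L)
  conc <- NULL
  nca_rows <- vector("list", n)
  n_failed <- 0L
  for (i in seq_len(n)) {
    row <- draws[i, , drop = FALSE]
    sim <- tryCatch(
      simulate_profile(ode_params_for_draw(model, row), regimen = regimen,
                       washout_h = washout_h, coarse_dt = coarse_dt, ...),
      error = function(e) NULL)
    if (is.null(sim)) {
      n_failed <- n_failed + 1L
      if (n_failed > nrow(extra)) {
        stop("more than 5% of Monte Carlo iterations failed", call. = FALSE)
      }
      row <- extra[n_failed, , drop = FALSE]
      sim <- simulate_profile(ode_params_for_draw(model, row),
                              regimen = regimen, washout_h = washout_h,
                              coarse_dt = coarse_dt, ...)
    }
    if (is.null(conc)) {
      conc <- matrix(NA_real_, n, length(sim$time))
      time <- sim$time
      template <- sim
    }
    conc[i, ] <- sim$conc
    r <- nca(sim)
    nca_rows[[i]] <- data.frame(iteration = i, cmax = r$cmax, tmax = r$tmax,
                                auc24 = r$auc24, t_half = r$t_half,
                                cl_f = r$cl_f, vd_f = r$vd_f)
  }
  bands <- t(apply(conc, 2, quantile, probs = c(0.025, 0.5, 0.975),
                   names = FALSE))
  colnames(bands) <- c("p2.5", "p50", "p97.5")
  median_sim <- template
  median_sim$conc <- bands[, "p50"]
  structure(list(time = time, bands = bands,
                 nca = do.call(rbind, nca_rows),
                 median_nca = nca(median_sim),
                 n = n, seed = seed, n_failed = n_failed,
                 regimen = regimen),
            class = "pbpk_mc")
}

#' @export
print.pbpk_mc <- function(x, ...) {
  cat(sprintf("Monte Carlo population simulation (n = %d, seed = %s)\n",
              x$n, format(x$seed)))
  cat(sprintf("  regimen: %g mg q%gh x %d; %d iteration(s) resampled\n",
              x$regimen$dose_mg, x$regimen$interval_h, x$regimen$n_doses,
              x$n_failed))
  cat("  median-curve NCA:\n")
  print(x$median_nca)
  invisible(x)
}

#' @export
plot.pbpk_mc <- function(x, final_interval = TRUE, ...) {
  idx <- if (final_interval) {
    x$time >= x$regimen$start_h + x$regimen$interval_h * (x$regimen$n_doses - 1)
  } else rep(TRUE, length(x$time))
  tt <- x$time[idx] - if (final_interval) min(x$time[idx]) else 0
  plot(tt, x$bands[idx, "p50"], type = "n",
       ylim = range(x$bands[idx, ]),
       xlab = if (final_interval) "time after last dose (h)" else "time (h)",
       ylab = "plasma concentration (ug/L)", ...)
  polygon(c(tt, rev(tt)), c(x$bands[idx, "p2.5"], rev(x$bands[idx, "p97.5"])),
          col = "#fdd0d0", border = NA)
  lines(tt, x$bands[idx, "p50"], col = "#cc2222", lwd = 2)
  invisible(x)
}
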