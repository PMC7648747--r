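test_that("noise-free calibration fixtures lie exactly on the model curve", {
  cal <- make_calibration_like(base_model, regimen(200, 24, 5), n_subjects = 2,
                               noise_cv = 0, seed = 1,
                               sample_times_h = seq(0, 24, by = 4))
  truth <- attr(cal, "truth")
  for (s in 1:2) {
    expect_equal(cal$conc_ug_per_L[cal$subject == s], truth$conc_ug_per_L)
  }
})

test_that("seeded fixture generation is reproducible and round-trips CSV", {
  a <- make_calibration_like(base_model, regimen(100, 24, 3), n_subjects = 3,
                             noise_cv = 0.2, seed = 7,
                             sample_times_h = seq(0, 24, by = 6))
  b <- make_calibration_like(base_model, regimen(100, 24, 3), n_subjects = 3,
                             noise_cv = 0.2, seed = 7,
                             sample_times_h = seq(0, 24, by = 6))
  expect_identical(as.data.frame(a), as.data.frame(b))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_observed(a, tmp)
  expect_equal(as.data.frame(read_observed(tmp)), as.data.frame(a),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("injected multiplicative noise reappears as per-timepoint sample CV", {
  cal <- make_calibration_like(base_model, n_subjects = 11, noise_cv = 0.2,
                               seed = 13)
  cvs <- vapply(split(cal$conc_ug_per_L, cal$time_h),
                function(x) stats::sd(x) / mean(x), numeric(1))
  expect_within(median(cvs), 0.1, 0.3)
})

test_that("verification fixtures show falling exposure from second to third
           trimester", {
  v <- make_verification_like(base_model, noise_cv = 0.1, seed = 3)
  paired <- intersect(v$subject[v$trimester == 2], v$subject[v$trimester == 3])
  t2 <- v[v$trimester == 2 & v$subject %in% paired, ]
  t3 <- v[v$trimester == 3 & v$subject %in% paired, ]
  expect_lt(mean(t3$cmax), mean(t2$cmax))
  expect_lt(mean(t3$auc24), mean(t2$auc24))
})

test_that("synthetic noise propagates to fold-error metrics at the expected
           magnitude", {
  # lognormal residual CV of 30% implies AAFE near 10^(0.8*sdlog/ln 10) ~ 1.26
  v <- make_verification_like(base_model, noise_cv = 0.3, seed = 1)
  ev <- evaluate_observed(v[, c("subject", "dose_mg", "ga_weeks",
                                "body_weight_kg", "cmax", "auc24")])
  for (s in ev$summaries) expect_within(s$aafe, 1.1, 1.6)
})

test_that("calibration parameters are recovered exactly from noise-free data", {
  truth <- c(ka_max = base_model$drug$absorption$ka_max,
             tau_a = base_model$drug$absorption$tau_a,
             cl_bile = base_model$drug$ehc$cl_bile,
             k_empty = base_model$drug$ehc$k_empty,
             clint = base_model$clearance$total)
  cal <- make_calibration_like(base_model, noise_cv = 0, seed = 1,
                               n_subjects = 1)
  fit <- pbpk_fit(base_model, cal,
                  start = truth * c(1.25, 1 / 1.25, 1.25, 1 / 1.25, 1.25))
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 0.01)
  expect_lt(max(abs(coef(fit) / truth - 1)), 0.01)
})

test_that("the clearance scalar is recovered within 15% under 20% noise", {
  truth_clint <- base_model$clearance$total
  start <- c(ka_max = base_model$drug$absorption$ka_max * 1.1,
             tau_a = base_model$drug$absorption$tau_a / 1.1,
             cl_bile = base_model$drug$ehc$cl_bile * 1.1,
             k_empty = base_model$drug$ehc$k_empty / 1.1,
             clint = truth_clint * 1.1)
  errs <- vapply(1:20, function(s) {
    cal <- make_calibration_like(base_model, noise_cv = 0.2, seed = s,
                                 n_subjects = 11)
    fit <- pbpk_fit(base_model, cal, start = start)
    abs(coef(fit)[["clint"]] / truth_clint - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})
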