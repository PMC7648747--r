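test_that("zero variability collapses every draw onto the mean", {
  spec <- distribution_spec("x", "lognormal", 10, 0)
  expect_equal(sertpbpk:::draw_truncated(spec, 50), rep(10, 50))
})

test_that("lognormal sampling is unbiased and respects truncation bounds", {
  spec <- distribution_spec("x", "lognormal", 5, 0.3)
  set.seed(3)
  x <- sertpbpk:::draw_truncated(spec, 1e4)
  expect_equal(mean(x), 5, tolerance = 0.02)
  expect_true(all(x >= spec$lower & x <= spec$upper))

  # large-sample truncation property, both families
  for (fam in c("lognormal", "normal")) {
    sp <- distribution_spec("y", fam, 2, 0.25)
    set.seed(17)
    y <- sertpbpk:::draw_truncated(sp, 1e5)
    expect_identical(sum(y < sp$lower | y > sp$upper), 0L)
  }
})

test_that("sampled fractional flows and volumes renormalize exactly", {
  specs <- default_distribution_specs(base_model)
  draws <- sample_parameters(specs, 200, seed = 5)
  qcols <- grep("^q_frac_", names(draws))
  expect_equal(unname(rowSums(draws[qcols])), rep(1, 200))
  vcols <- grep("^v_frac_", names(draws))
  vtarget <- sum(unlist(base_model$physiology$volume_fractions))
  expect_equal(unname(rowSums(draws[vcols])), rep(vtarget, 200))
})

test_that("identical seeds reproduce draws and Monte Carlo output bitwise", {
  specs <- default_distribution_specs(base_model)
  expect_identical(sample_parameters(specs, 20, seed = 8),
                   sample_parameters(specs, 20, seed = 8))
  mc1 <- monte_carlo(base_model, regimen(100, 24, 5), n = 8, seed = 21,
                     washout_h = 24)
  mc2 <- monte_carlo(base_model, regimen(100, 24, 5), n = 8, seed = 21,
                     washout_h = 24)
  expect_identical(mc1$bands, mc2$bands)
  expect_identical(mc1$nca, mc2$nca)
})

test_that("with all CVs zero the population bands collapse onto the
           deterministic curve", {
  specs <- default_distribution_specs(base_model, cv_kp = 0, cv_phys = 0,
                                      cv_drug = 0)
  mc <- monte_carlo(base_model, regimen(100, 24, 5), n = 5, seed = 1,
                    washout_h = 24, coarse_dt = 3)
  det <- simulate_profile(base_model, regimen(100, 24, 5), washout_h = 24,
                          coarse_dt = 3)
  mc0 <- monte_carlo(base_model, regimen(100, 24, 5), n = 5, seed = 1,
                     specs = specs, washout_h = 24, coarse_dt = 3)
  expect_equal(mc0$bands[, "p2.5"], det$conc, tolerance = 1e-10)
  expect_equal(mc0$bands[, "p97.5"], det$conc, tolerance = 1e-10)
  # and with variability on, the band has positive width
  expect_true(any(mc$bands[, "p97.5"] > mc$bands[, "p2.5"]))
})

test_that("infeasible distribution requests are spec errors", {
  expect_error(distribution_spec("x", "lognormal", 5, -0.1), "cv")
  expect_error(distribution_spec("x", "normal", 0, 0.3), "mean")
  expect_error(sample_parameters(default_distribution_specs(base_model), 0,
                                 seed = 1), "n must be")
})
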