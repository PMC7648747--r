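test_that("time-dependent absorption starts at zero and saturates", {
  expect_equal(ka_t(0, 0.5, 2), 0)
  expect_equal(ka_t(1e4, 0.5, 2), 0.5)
  kas <- ka_t(seq(0, 10, by = 0.5), 0.5, 2)
  expect_true(all(diff(kas) > 0))
  expect_error(ka_t(1, 0.5, 0), "tau_a")
  expect_error(ka_t(-1, 0.5, 2), ">= 0")
})

test_that("derivatives vanish at the empty state (no zero-order terms)", {
  y <- setNames(numeric(8), c("gut_lumen", "gallbladder", "gut", "liver",
                              "plasma", "richly_perfused", "slowly_perfused",
                              "metabolized"))
  d <- pbpk_derivatives(y, 5, base_model$params)
  expect_equal(unname(d), numeric(8))
})

test_that("compiled and R right-hand sides integrate to the same curve", {
  sim_c <- simulate_profile(base_model, short_reg, washout_h = 48)
  sim_r <- simulate_profile(base_model, short_reg, washout_h = 48,
                            compiled = FALSE)
  expect_equal(sim_r$conc, sim_c$conc, tolerance = 1e-6)
})

test_that("with constant absorption and no biliary secretion the model is the
           classical linear oral system (matrix-exponential oracle)", {
  skip_if_not_installed("Matrix")
  p <- base_model$params
  p[["CL_bile"]] <- 0
  p[["ka_max"]] <- 0.3
  sim <- simulate_profile(p, regimen(100, 24, 1), washout_h = 48,
                          ka_constant = TRUE)
  # independent solution: x'(t) = A x, x0 = dose in the lumen
  ka <- 0.3
  V <- p[c("V_plasma", "V_gut", "V_liver", "V_richly", "V_slowly")]
  Q <- p[c("Q_gut", "Q_hepatic_arterial", "Q_richly", "Q_slowly")]
  K <- p[c("Kp_gut", "Kp_liver", "Kp_richly", "Kp_slowly")]
  ex <- p[["fu"]] * p[["CLint"]]
  # states: lumen, gut, liver, plasma, rich, slow
  A <- matrix(0, 6, 6)
  A[1, 1] <- -ka
  A[2, 1] <- ka
  A[2, 2] <- -Q[["Q_gut"]] / (V[["V_gut"]] * K[["Kp_gut"]])
  A[2, 4] <- Q[["Q_gut"]] / V[["V_plasma"]]
  A[3, 2] <- Q[["Q_gut"]] / (V[["V_gut"]] * K[["Kp_gut"]])
  A[3, 3] <- -(Q[["Q_gut"]] + Q[["Q_hepatic_arterial"]] + ex) /
    (V[["V_liver"]] * K[["Kp_liver"]])
  A[3, 4] <- Q[["Q_hepatic_arterial"]] / V[["V_plasma"]]
  A[4, 3] <- (Q[["Q_gut"]] + Q[["Q_hepatic_arterial"]]) /
    (V[["V_liver"]] * K[["Kp_liver"]])
  A[4, 4] <- -(Q[["Q_gut"]] + Q[["Q_hepatic_arterial"]] + Q[["Q_richly"]] +
                 Q[["Q_slowly"]]) / V[["V_plasma"]]
  A[4, 5] <- Q[["Q_richly"]] / (V[["V_richly"]] * K[["Kp_richly"]])
  A[4, 6] <- Q[["Q_slowly"]] / (V[["V_slowly"]] * K[["Kp_slowly"]])
  A[5, 4] <- Q[["Q_richly"]] / V[["V_plasma"]]
  A[5, 5] <- -Q[["Q_richly"]] / (V[["V_richly"]] * K[["Kp_richly"]])
  A[6, 4] <- Q[["Q_slowly"]] / V[["V_plasma"]]
  A[6, 6] <- -Q[["Q_slowly"]] / (V[["V_slowly"]] * K[["Kp_slowly"]])
  x0 <- c(100000, 0, 0, 0, 0, 0)
  for (tt in c(1, 6, 24, 48)) {
    x <- as.numeric(Matrix::expm(A * tt) %*% x0)
    got <- sim$conc[which.min(abs(sim$time - tt))]
    expect_equal(got, x[4] / V[["V_plasma"]], tolerance = 1e-6)
  }
})

test_that("without elimination all tissues equilibrate to their Kp", {
  p <- base_model$params
  p[["CLint"]] <- 0
  p[["CL_bile"]] <- 0
  p[["ka_max"]] <- 2
  sim <- simulate_profile(p, regimen(100, 24, 1), washout_h = 5000,
                          ka_constant = TRUE, fine_dt = 10, coarse_dt = 10)
  last <- sim$amounts[nrow(sim$amounts), ]
  c_pl <- last[["plasma"]] / p[["V_plasma"]]
  expect_equal(last[["gut"]] / p[["V_gut"]] / c_pl, p[["Kp_gut"]],
               tolerance = 1e-4)
  expect_equal(last[["liver"]] / p[["V_liver"]] / c_pl, p[["Kp_liver"]],
               tolerance = 1e-4)
  expect_equal(last[["richly_perfused"]] / p[["V_richly"]] / c_pl,
               p[["Kp_richly"]], tolerance = 1e-4)
  expect_equal(last[["slowly_perfused"]] / p[["V_slowly"]] / c_pl,
               p[["Kp_slowly"]], tolerance = 1e-4)
})

test_that("mass is conserved and amounts stay non-negative", {
  sim <- simulate_profile(base_model, regimen(200, 24, 30), washout_h = 72)
  expect_lt(mass_balance_error(sim), 1e-3)
  expect_true(all(sim$amounts >= 0))
  expect_true(all(diff(sim$time) > 0))

  # also across a handful of sampled population parameter sets
  specs <- default_distribution_specs(base_model)
  draws <- sample_parameters(specs, 5, seed = 99)
  for (i in 1:5) {
    p <- sertpbpk:::ode_params_for_draw(base_model, draws[i, ])
    s <- simulate_profile(p, short_reg, washout_h = 24)
    expect_lt(mass_balance_error(s), 1e-3)
    expect_true(all(s$amounts >= 0))
  }
})

test_that("zero dose gives identically zero concentrations", {
  sim <- simulate_profile(base_model, regimen(0, 24, 3), washout_h = 24)
  expect_true(all(sim$conc == 0))
})

test_that("kinetics are linear in dose to numerical precision", {
  s1 <- simulate_profile(base_model, regimen(50, 24, 10), washout_h = 24)
  s2 <- simulate_profile(base_model, regimen(100, 24, 10), washout_h = 24)
  r1 <- nca(s1); r2 <- nca(s2)
  expect_equal(r2$cmax / r1$cmax, 2, tolerance = 1e-6)
  expect_equal(r2$auc24 / r1$auc24, 2, tolerance = 1e-6)
})

test_that("the multi-dose curve is the superposition of shifted single doses
           when absorption is time-invariant", {
  p <- base_model$params
  single <- simulate_profile(p, regimen(100, 24, 1), washout_h = 96,
                             ka_constant = TRUE, fine_dt = 0.5)
  multi <- simulate_profile(p, regimen(100, 24, 3), washout_h = 48,
                            ka_constant = TRUE, fine_dt = 0.5,
                            coarse_dt = 0.5)
  tt <- seq(49, 70, by = 0.5)
  sup <- approx(single$time, single$conc, xout = tt)$y +
    approx(single$time, single$conc, xout = tt - 24)$y +
    approx(single$time, single$conc, xout = tt - 48)$y
  got <- approx(multi$time, multi$conc, xout = tt)$y
  expect_equal(got, sup, tolerance = 1e-5)
})

test_that("steady-state accumulation is consistent with the terminal half-life", {
  first <- simulate_profile(base_model, regimen(200, 24, 1), washout_h = 24)
  auc1 <- nca(first, interval_h = 24, dose_mg = 200)$auc24
  ss <- simulate_profile(base_model, regimen(200, 24, 30), washout_h = 72)
  r <- nca(ss)
  racc_pred <- 1 / (1 - 2^(-24 / r$t_half))
  expect_equal(r$auc24 / auc1, racc_pred, tolerance = 0.1)
  # slow absorption: peak well after dosing, within the reported window
  expect_within(r$tmax, 3, 8)
})

test_that("regimen validation rejects degenerate inputs", {
  expect_error(regimen(-1), ">= 0")
  expect_error(regimen(100, 0), "> 0")
  expect_error(regimen(100, 24, 0), ">= 1")
})
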