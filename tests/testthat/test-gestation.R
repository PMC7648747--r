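test_that("gestational state at GA 0 reproduces nonpregnant physiology exactly", {
  st <- gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, 0, fu0 = 0.015)
  ph <- pkg_cfg$physiology
  comps <- c("plasma", "gut", "liver", "richly_perfused", "slowly_perfused")
  expect_identical(unname(st$volumes),
                   unname(unlist(ph$volume_fractions[comps])) * ph$body_weight0)
  expect_identical(st$body_weight, ph$body_weight0)
  expect_identical(st$cardiac_output, ph$cardiac_output0)
  expect_identical(st$fu, 0.015)
  expect_identical(unname(st$cyp_multipliers), rep(1, 5))
  expect_identical(st$placental_fetal_volume, 0)
})

test_that("gestational trajectories are monotone and flows track cardiac output", {
  gas <- seq(0, 40, by = 2)
  states <- lapply(gas, function(g) {
    gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, g, fu0 = 0.015)
  })
  pull <- function(f) vapply(states, f, numeric(1))
  expect_true(all(diff(pull(function(s) s$body_weight)) >= 0))
  expect_true(all(diff(pull(function(s) s$cardiac_output)) >= 0))
  expect_true(all(diff(pull(function(s) s$placental_fetal_volume)) >= 0))
  expect_true(all(diff(pull(function(s) s$fu)) >= 0))
  expect_true(all(diff(pull(function(s) s$cyp_multipliers[["CYP3A4"]])) >= 0))
  for (s in states) {
    expect_equal(sum(s$flows), s$cardiac_output)
    expect_true(all(unlist(s$volumes) > 0))
  }
  # weight gain is strictly increasing between trimesters
  bw <- pull(function(s) s$body_weight)
  expect_gt(bw[gas == 20], bw[gas == 10])
})

test_that("fraction unbound rises by roughly 3/12/27% at representative trimester ages", {
  fu0 <- 0.015
  rise <- vapply(c(7, 20, 34), function(g) {
    st <- gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, g, fu0 = fu0)
    100 * (st$fu / fu0 - 1)
  }, numeric(1))
  expect_within(rise[1], 3 - 3, 3 + 3)
  expect_within(rise[2], 12 - 3, 12 + 3)
  expect_within(rise[3], 27 - 3, 27 + 3)
})

test_that("albumin-scaled binding model matches its closed form", {
  expect_identical(fu_at_ga(0.015, 1), 0.015)
  # direct evaluation of fu = fu0/(fu0 + (1-fu0)*a) at a = 0.5
  expect_equal(fu_at_ga(0.015, 0.5), 0.015 / (0.015 + 0.985 * 0.5))
  expect_equal(fu_at_ga(0.015, 0.5), 0.0296, tolerance = 2e-3)
  # binding can only loosen when albumin falls
  for (a in seq(0.2, 1, by = 0.1)) {
    for (f in c(0.01, 0.1, 0.5, 0.9)) {
      expect_gte(fu_at_ga(f, a), f)
    }
  }
  expect_error(fu_at_ga(1.5, 1), "fu0")
  expect_error(fu_at_ga(0.015, 0), "albumin_ratio")
  expect_error(fu_at_ga(0.015, 1.5), "albumin_ratio")
})

test_that("gestational age domain is enforced", {
  expect_error(gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, -1), ">= 0")
  expect_error(gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, 50), "42")
  expect_error(ga_eval(pkg_cfg$gestation$albumin_ratio, -2), ">= 0")
})

test_that("pre-pregnancy weight back-calculation inverts the gain function", {
  for (g in c(5, 18, 33)) {
    st <- gestation_scale(pkg_cfg$physiology, pkg_cfg$gestation, g)
    expect_equal(prepregnancy_weight(st$body_weight, g, pkg_cfg$gestation),
                 pkg_cfg$physiology$body_weight0)
  }
})
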