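test_that("a tissue with plasma composition and equal binding partitions at unity", {
  comp <- tissue_composition_table()
  self <- comp[comp$tissue == "plasma", ]
  self$tissue <- "mock"
  self$lump <- "richly_perfused"; self$volume_L <- 1
  expect_equal(kp_poulin_haddad(5.29, 0.015, rbind(comp, self), "mock",
                                fu_t = 0.015), 1)
})

test_that("Kp is non-decreasing in logP for lipid-rich tissue", {
  kps <- vapply(c(2, 3, 4, 5, 6), function(lp) {
    kp_poulin_haddad(lp, 0.015, tissue = "adipose")
  }, numeric(1))
  expect_true(all(diff(kps) >= 0))
})

test_that("partitioning matches a direct evaluation of the composition formula", {
  set.seed(4)
  comp <- tissue_composition_table()
  pl <- comp[comp$tissue == "plasma", ]
  for (i in 1:10) {
    row <- data.frame(tissue = "rand",
                      f_water = runif(1, 0.2, 0.9),
                      f_neutral_lipid = runif(1, 0.001, 0.5),
                      f_phospholipid = runif(1, 0.001, 0.05),
                      lump = "slowly_perfused", volume_L = 1)
    logP <- runif(1, 1, 6)
    fu0 <- runif(1, 0.01, 0.5)
    got <- kp_poulin_haddad(logP, fu0, rbind(comp, row), "rand")
    # independent one-line recomputation of the published equation
    P <- 10^logP
    num <- P * (row$f_neutral_lipid + 0.3 * row$f_phospholipid) +
      row$f_water + 0.7 * row$f_phospholipid
    den <- P * (pl$f_neutral_lipid + 0.3 * pl$f_phospholipid) +
      pl$f_water + 0.7 * pl$f_phospholipid
    fut <- 1 / (1 + 0.5 * (1 - fu0) / fu0)
    expect_equal(got, (num / den) * fu0 / fut, tolerance = 1e-9)
  }
})

test_that("lumped Kp is the volume-weighted member aggregate", {
  comp <- tissue_composition_table()
  kp <- kp_compartments(5.29, 0.015, comp)
  slow <- comp[!is.na(comp$lump) & comp$lump == "slowly_perfused", ]
  member <- vapply(slow$tissue, function(tt) {
    kp_poulin_haddad(5.29, 0.015, comp, tt)
  }, numeric(1))
  expect_equal(kp[["slowly_perfused"]],
               sum(member * slow$volume_L) / sum(slow$volume_L))

  # degenerate case: identical members collapse onto the shared value
  same <- comp[comp$tissue %in% c("plasma", "muscle"), ]
  twin <- same[same$tissue == "muscle", ]
  twin$tissue <- "muscle2"; twin$volume_L <- 5
  comp2 <- rbind(same, twin)
  comp2$lump[comp2$tissue != "plasma"] <- "slowly_perfused"
  kp2 <- kp_compartments(5.29, 0.015, comp2)
  expect_equal(kp2[["slowly_perfused"]],
               kp_poulin_haddad(5.29, 0.015, comp2, "muscle"))
})

test_that("adjustment factors act element-wise and identity leaves Kp unchanged", {
  raw <- kp_compartments(5.29, 0.015)
  id <- apply_adjustment(raw, list())
  expect_equal(id$kp, raw)
  doubled <- apply_adjustment(raw, list(liver = 2))
  expect_equal(doubled$kp[["liver"]], 2 * raw[["liver"]])
  expect_equal(doubled$kp[["gut"]], raw[["gut"]])
  expect_error(apply_adjustment(raw, list(liver = -1)), "> 0")
})

test_that("unknown tissues are lookup errors", {
  expect_error(kp_poulin_haddad(5.29, 0.015, tissue = "spleen"), "unknown tissue")
})
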