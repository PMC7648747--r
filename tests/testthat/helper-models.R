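# shared fixtures: built once per test run
pkg_cfg <- load_config()
base_model <- pbpk_model()

# a small regimen for fast structural checks
short_reg <- regimen(100, 24, 3)

expect_within <- function(value, lower, upper) {
  expect_gte(value, lower)
  expect_lte(value, upper)
}
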