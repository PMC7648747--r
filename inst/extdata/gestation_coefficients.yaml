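# Gestational-age scaling functions (gestational age in weeks).
#
# Shapes follow the pregnancy-physiology literature (quadratic weight
# gain, plasma-volume expansion and albumin decline; near-linear
# placental-fetal growth in volume-squared terms; saturating hormone-
# driven CYP induction). Coefficients were fixed once so that the model
# reproduces the established aggregate trajectories: ~12.5 kg weight gain
# and ~45% plasma-volume expansion at term, albumin falling to ~73% of the
# nonpregnant level, fraction-unbound increases of ~3/12/27% by trimester,
# and total hepatic intrinsic clearance rising ~11/37/63% at gestational
# weeks 10/20/30. Every function evaluates to its nonpregnant reference
# (gain 0, ratio 1) at gestational age 0.
body_weight_gain_kg:
  form: polynomial
  coefficients: [0.0, 0.0461, 0.00665]
plasma_volume_ratio:
  form: polynomial
  coefficients: [1.0, 0.0, 2.8e-4]
cardiac_output_ratio:
  form: polynomial
  coefficients: [1.0, 0.019, -2.375e-4]
placental_fetal_volume_L:
  form: polynomial
  coefficients: [0.0, 0.0, 0.003]
albumin_ratio:
  form: polynomial
  coefficients: [1.0, -0.0036, -8.065e-5]
cyp3a4_multiplier:
  form: sigmoid                 # 1 + amplitude * (S(ga) - S(0))
  amplitude: 1.2222
  midpoint: 21                  # weeks
  width: 8                      # weeks
cyp2d6_multiplier:
  form: polynomial
  coefficients: [1.0, 0.02]
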