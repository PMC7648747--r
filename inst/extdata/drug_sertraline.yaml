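# Sertraline drug parameter set.
#
# Physicochemical constants are public-compendium values. The per-CYP
# kinetic table (vmax pmol/min/pmol CYP at 0.5 uM substrate, inter-system
# extrapolation factor, hepatic abundance pmol/mg microsomal protein) is a
# SYNTHETIC reconstruction: the original recombinant-enzyme report is not
# redistributable, so plausible-magnitude constants were fixed once such
# that the IVIVE chain yields the model's nonpregnant CYP contribution
# shares (CYP3A4/2B6/2C9/2C19/2D6 = 73/9/8/7/3% of total hepatic intrinsic
# clearance). The calibration block (clearance scalar, partition
# adjustment factors, absorption and enterohepatic constants) was fitted
# once against the nonpregnancy steady-state profile and frozen; it is
# never re-fitted at run time.
name: sertraline
molecular_weight: 306.23        # g/mol
logP: 5.29
pKa: 9.47
fu0: 0.015                      # fraction unbound in plasma (98.5% bound)
fu_mic: 1.0                     # fraction unbound in microsomal incubation
blood_plasma_ratio: 1.0
tablet_strengths_mg: [25, 50, 100]
substrate_conc_uM: 0.5
cyp_kinetics:
  CYP3A4:  {vmax: 2.7, isef: 0.2000, abundance: 137}
  CYP2B6:  {vmax: 4.3, isef: 0.1247, abundance: 17}
  CYP2C9:  {vmax: 0.6, isef: 0.1850, abundance: 73}
  CYP2C19: {vmax: 2.2, isef: 0.2302, abundance: 14}
  CYP2D6:  {vmax: 1.4, isef: 0.2713, abundance: 8}
clint_calibration_factor: 6.3329
absorption:
  ka_max: 0.201                  # 1/h, asymptotic absorption rate
  tau_a: 1.706                    # h, dissolution time constant
ehc:
  cl_bile: 400                  # L/h on unbound liver concentration
  k_empty: 0.35                 # 1/h, gallbladder emptying
kp_adjustment:                  # calibrated tissue-partition factors
  gut: 1.518
  liver: 1.518
  richly_perfused: 9.242
  slowly_perfused: 4.199
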