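# Reference nonpregnant adult female physiology (compendial reference
# values for a 60-kg woman). Volume fractions are of body weight at unit
# tissue density; the five model compartments intentionally do not cover
# whole-body mass (erythrocytes, lung, residual structures are excluded
# from drug distribution). Flow fractions are of cardiac output and sum to
# exactly 1 after lumping.
body_weight0: 60          # kg
cardiac_output0: 300      # L/h (5.0 L/min)
liver_mass: 1400          # g
mppgl: 40                 # mg microsomal protein per g liver
volume_fractions:
  plasma: 0.0417
  gut: 0.017
  liver: 0.0233
  richly_perfused: 0.075
  slowly_perfused: 0.75
flow_fractions:
  gut: 0.15
  liver_arterial: 0.065
  richly_perfused: 0.47
  slowly_perfused: 0.315
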