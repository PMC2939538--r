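# Example configuration for the osmoreg simulator.
# Omitted keys keep their defaults; tables are (x, y) knot lists.

days: 20
seed: 1
protocol: control

weight: 255          # g
ecf_na_conc_init: 140  # mmol/L, also the drinking set-point

drinking:
  bout_volume_ml: 1
  p_base: 0.24       # per-minute supply envelope of unregulated bouts
  p_amplitude: 1.0

gut:
  k_stomach_intestine: 0.018   # gastric emptying, per minute

# aldosterone stage: fractional ECF deficit -> plasma ALD (ng/100 ml)
ald_volume_table:
  x: [0.0, 0.02, 0.05, 0.10]
  "y": [0, 40, 120, 200]
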