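# Reference simulation input parameters.
# Values merge over the package defaults; this file states the headline
# hemodynamic conditions explicitly.
general:
  hr_bpm: 71
  co_L_min: 5.1
  map_mmHg: 91
  systolic_duration_frac: 0.41
coronary_targets:
  RCA:
    q0_mL_min: 112
  LAD:
    q0_mL_min: 83
  LCx:
    q0_mL_min: 60
  endo_epi_ratio: 1.11
walls:
  RV:
    wall_volume_mL: 39
  S:
    wall_volume_mL: 45
  LV:
    wall_volume_mL: 108
valves:
  aortic:
    A_open_cm2: 4.8
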