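environment:
  water_As:
    family: lognormal
    calibrate_from_range:
      lo: 0.000735
      hi: 0.11
      coverage: 0.986111111111
    units: mg/L
  soil_As:
    family: uniform
    lo: 1.92
    hi: 7.91
    units: mg/kg
  lake_As:
    family: uniform
    lo: 0.005
    hi: 0.0097
    units: mg/L
  clam_total_As_dw:
    family: truncated_normal
    mean: 5.67
    sd: 3.0
    lo: 0.0
    hi: 14.67
    units: mg/kg
  BAF:
    family: uniform
    lo: 10.3
    hi: 22.0
    units: '1'
  dry_season_multiplier:
    family: truncated_normal
    mean: 6.71
    sd: 4.5
    lo: 2.21
    hi: 13.66
    units: '1'
  aquatic_iAs_fraction:
    family: uniform
    lo: 0.117
    hi: 0.142
    units: '1'
transfer_factors:
  rice:
    family: uniform
    lo: 0.006
    hi: 0.036
    units: '1'
  corn:
    family: uniform
    lo: 0.005
    hi: 0.027
    units: '1'
  vegetables:
    family: uniform
    lo: 0.0003
    hi: 0.028
    units: '1'
  root_crops:
    family: uniform
    lo: 0.0028
    hi: 0.007
    units: '1'
intakes:
  fish:
    family: truncated_normal
    mean: 59.0
    sd: 488.8
    lo: 0.0
    hi: 1525.4
    units: g/day
  clam:
    family: truncated_normal
    mean: 8.5
    sd: 70.4
    lo: 0.0
    hi: 219.7
    units: g/day
  rice:
    family: truncated_normal
    mean: 263.0
    sd: 872.8
    lo: 0.0
    hi: 2881.4
    units: g/day
  corn:
    family: truncated_normal
    mean: 6.0
    sd: 541.2
    lo: 0.0
    hi: 1629.6
    units: g/day
  vegetables:
    family: truncated_normal
    mean: 58.0
    sd: 680.8
    lo: 0.0
    hi: 2100.4
    units: g/day
  root_crops:
    family: truncated_normal
    mean: 7.0
    sd: 104.7
    lo: 0.0
    hi: 321.1
    units: g/day
  water:
    family: point
    value: 1.791
    units: L/day
anthropometry:
  prop_male: 0.506
  male:
    body_weight:
      family: truncated_normal
      mean: 61.3
      sd: 9.0
      lo: 40.0
      hi: 155.0
      units: kg
    height:
      family: truncated_normal
      mean: 163.0
      sd: 6.5
      lo: 60.0
      hi: 220.0
      units: cm
  female:
    body_weight:
      family: truncated_normal
      mean: 54.3
      sd: 8.5
      lo: 35.0
      hi: 145.0
      units: kg
    height:
      family: truncated_normal
      mean: 154.0
      sd: 6.0
      lo: 55.0
      hi: 210.0
      units: cm
risk:
  rfd: 0.06
  csf: 0.032
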