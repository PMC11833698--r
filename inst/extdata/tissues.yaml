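gelatin:
  f_water: 0.95
  f_lipid: 0.0
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 3.0
  musp_b: 1.0
  g: 0.9
  'n': 1.35
porcine_muscle:
  f_water: 0.72
  f_lipid: 0.1
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 521.1
  musp_b: 5.0
  g: 0.9
  'n': 1.37
skin:
  f_water: 0.6
  f_lipid: 0.1
  c_HbO2_M: 2.0e-05
  c_Hb_M: 2.0e-05
  musp_a: 45.0
  musp_b: 1.4
  g: 0.9
  'n': 1.4
fat:
  f_water: 0.15
  f_lipid: 0.75
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 32.0
  musp_b: 0.7
  g: 0.9
  'n': 1.44
kidney:
  f_water: 0.65
  f_lipid: 0.03
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 23.0
  musp_b: 1.5
  g: 0.9
  'n': 1.37
blood:
  f_water: 0.0
  f_lipid: 0.0
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 7.0
  musp_b: 1.0
  g: 0.98
  'n': 1.36
PBS:
  f_water: 1.0
  f_lipid: 0.0
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 0.1
  musp_b: 1.0
  g: 0.0
  'n': 1.33
tube_wall:
  f_water: 0.0
  f_lipid: 0.0
  c_HbO2_M: 0.0
  c_Hb_M: 0.0
  musp_a: 30.0
  musp_b: 0.5
  g: 0.9
  'n': 1.35
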