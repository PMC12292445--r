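name: vardenafil
molecular_weight_g_mol: 488.61
logp: 1.97
pka:
- value: 4.24
  kind: base
- value: 7.76
  kind: base
- value: 8.68
  kind: acid
solubility_mg_ml:
- ph: 1.0
  value: 30.0
- ph: 3.0
  value: 30.0
- ph: 5.0
  value: 27.4
- ph: 7.0
  value: 0.05
peff_cm_s: 0.0005
particle_diameter_um: 100.0
particle_density_g_ml: 1.2
precipitation_time_s: 900.0
first_pass_effect_percent: 83.0
clearance_l_h_kg: 0.925
central_volume_l_kg: 0.8
k12_1_h: 3.09
k21_1_h: 2.1
k13_1_h: 0.448
k31_1_h: 0.25
body_weight_kg: 70.0
diffusion_coeff_cm2_s: 5.913e-06
blood_plasma_ratio: 0.83
fraction_unbound_percent: 5.0
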