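# Cynomolgus monkey physiology (5 kg). Sources: cardiac output 1086 mL/min and
# blood volume ~74 mL/kg from Davies & Morris (1993); GFR 2.5 mL/min/kg
# (mid-range of reported cynomolgus iohexol/creatinine clearances, 2.0-3.5);
# fractional organ weights/flows from primate compilations (Brown et al. 1997
# and non-human-primate PBPK literature). Tissue composition from Poulin &
# Theil (2002); primate plasma composition taken as human.
# Units and conventions as in human.yaml.
species: monkey
body_weight_kg: 5
cardiac_output_L_h: 65.2       # 1086 mL/min
gfr_L_h: 0.75                  # 2.5 mL/min/kg x 5 kg
blood_volume_L: 0.368          # ~74 mL/kg
plasma_composition: {neutral_lipid: 0.0035, phospholipid: 0.00225, water: 0.945}
tissues:
  - {name: lung,    flow_frac: 1.000, volume_frac: 0.0070, ecf: 0.35, composition: {neutral_lipid: 0.0219, phospholipid: 0.0140, water: 0.811}}
  - {name: liver,   flow_frac: 0.055, volume_frac: 0.0270, ecf: 0.25, composition: {neutral_lipid: 0.0138, phospholipid: 0.0303, water: 0.705}}
  - {name: kidney,  flow_frac: 0.140, volume_frac: 0.0040, ecf: 0.30, composition: {neutral_lipid: 0.0123, phospholipid: 0.0284, water: 0.771}}
  - {name: gut,     flow_frac: 0.140, volume_frac: 0.0350, ecf: 0.30, composition: {neutral_lipid: 0.0292, phospholipid: 0.0138, water: 0.749}}
  - {name: spleen,  flow_frac: 0.020, volume_frac: 0.0020, ecf: 0.30, composition: {neutral_lipid: 0.0077, phospholipid: 0.0136, water: 0.771}}
  - {name: heart,   flow_frac: 0.050, volume_frac: 0.0040, ecf: 0.22, composition: {neutral_lipid: 0.0140, phospholipid: 0.0118, water: 0.779}}
  - {name: brain,   flow_frac: 0.060, volume_frac: 0.0200, ecf: 0.04, composition: {neutral_lipid: 0.0392, phospholipid: 0.0533, water: 0.788}}
  - {name: muscle,  flow_frac: 0.140, volume_frac: 0.4000, ecf: 0.14, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
  - {name: adipose, flow_frac: 0.040, volume_frac: 0.0500, ecf: 0.15, composition: {neutral_lipid: 0.8530, phospholipid: 0.0016, water: 0.120}}
  - {name: skin,    flow_frac: 0.060, volume_frac: 0.1000, ecf: 0.35, composition: {neutral_lipid: 0.0239, phospholipid: 0.0180, water: 0.651}}
  - {name: bone,    flow_frac: 0.050, volume_frac: 0.0700, ecf: 0.12, composition: {neutral_lipid: 0.0273, phospholipid: 0.0027, water: 0.446}}
  - {name: rest,    flow_frac: 0.245, volume_frac: 0.2074, ecf: 0.20, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
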