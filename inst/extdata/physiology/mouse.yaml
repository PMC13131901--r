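# Mouse physiology (25 g). Sources: fractional organ weights/flows from Brown
# et al. (1997) Toxicol Ind Health 13:407; cardiac output ~14 mL/min; blood
# volume 72 mL/kg and GFR 14 mL/min/kg from Davies & Morris (1993) Pharm Res
# 10:1093 compilations. Tissue composition from Poulin & Theil (2002), rat
# values reused; rodent plasma composition from the same source.
# Units and conventions as in human.yaml (lung in series; liver flow_frac is
# hepatic artery only; rest-of-body closes volume and flow balances).
species: mouse
body_weight_kg: 0.025
cardiac_output_L_h: 0.84       # 14 mL/min
gfr_L_h: 0.021                 # 14 mL/min/kg x 0.025 kg
blood_volume_L: 0.0018         # 72 mL/kg
plasma_composition: {neutral_lipid: 0.00147, phospholipid: 0.00083, water: 0.960}
tissues:
  - {name: lung,    flow_frac: 1.000, volume_frac: 0.0070, ecf: 0.35, composition: {neutral_lipid: 0.0219, phospholipid: 0.0140, water: 0.811}}
  - {name: liver,   flow_frac: 0.020, volume_frac: 0.0550, ecf: 0.25, composition: {neutral_lipid: 0.0138, phospholipid: 0.0303, water: 0.705}}
  - {name: kidney,  flow_frac: 0.091, volume_frac: 0.0170, ecf: 0.30, composition: {neutral_lipid: 0.0123, phospholipid: 0.0284, water: 0.771}}
  - {name: gut,     flow_frac: 0.141, volume_frac: 0.0420, ecf: 0.30, composition: {neutral_lipid: 0.0292, phospholipid: 0.0138, water: 0.749}}
  - {name: spleen,  flow_frac: 0.010, volume_frac: 0.0035, ecf: 0.30, composition: {neutral_lipid: 0.0077, phospholipid: 0.0136, water: 0.771}}
  - {name: heart,   flow_frac: 0.066, volume_frac: 0.0050, ecf: 0.22, composition: {neutral_lipid: 0.0140, phospholipid: 0.0118, water: 0.779}}
  - {name: brain,   flow_frac: 0.033, volume_frac: 0.0170, ecf: 0.04, composition: {neutral_lipid: 0.0392, phospholipid: 0.0533, water: 0.788}}
  - {name: muscle,  flow_frac: 0.159, volume_frac: 0.3840, ecf: 0.14, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
  - {name: adipose, flow_frac: 0.070, volume_frac: 0.0700, ecf: 0.15, composition: {neutral_lipid: 0.8530, phospholipid: 0.0016, water: 0.120}}
  - {name: skin,    flow_frac: 0.058, volume_frac: 0.1650, ecf: 0.35, composition: {neutral_lipid: 0.0239, phospholipid: 0.0180, water: 0.651}}
  - {name: bone,    flow_frac: 0.050, volume_frac: 0.0700, ecf: 0.12, composition: {neutral_lipid: 0.0273, phospholipid: 0.0027, water: 0.446}}
  - {name: rest,    flow_frac: 0.302, volume_frac: 0.0925, ecf: 0.20, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
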