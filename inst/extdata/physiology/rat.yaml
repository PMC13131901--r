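# Rat physiology (250 g). Sources: fractional organ weights/flows from Brown
# et al. (1997) Toxicol Ind Health 13:407; cardiac output 74 mL/min, blood
# volume 54 mL/kg, GFR 1.31 mL/min (5.2 mL/min/kg) from Davies & Morris (1993).
# Tissue composition from Poulin & Theil (2002); rodent plasma composition.
# Units and conventions as in human.yaml.
species: rat
body_weight_kg: 0.25
cardiac_output_L_h: 4.44       # 74 mL/min
gfr_L_h: 0.0786                # 1.31 mL/min
blood_volume_L: 0.0135         # 54 mL/kg
plasma_composition: {neutral_lipid: 0.00147, phospholipid: 0.00083, water: 0.960}
tissues:
  - {name: lung,    flow_frac: 1.0000, volume_frac: 0.0050, ecf: 0.35, composition: {neutral_lipid: 0.0219, phospholipid: 0.0140, water: 0.811}}
  - {name: liver,   flow_frac: 0.0210, volume_frac: 0.0366, ecf: 0.25, composition: {neutral_lipid: 0.0138, phospholipid: 0.0303, water: 0.705}}
  - {name: kidney,  flow_frac: 0.1410, volume_frac: 0.0073, ecf: 0.30, composition: {neutral_lipid: 0.0123, phospholipid: 0.0284, water: 0.771}}
  - {name: gut,     flow_frac: 0.1310, volume_frac: 0.0270, ecf: 0.30, composition: {neutral_lipid: 0.0292, phospholipid: 0.0138, water: 0.749}}
  - {name: spleen,  flow_frac: 0.0128, volume_frac: 0.0020, ecf: 0.30, composition: {neutral_lipid: 0.0077, phospholipid: 0.0136, water: 0.771}}
  - {name: heart,   flow_frac: 0.0510, volume_frac: 0.0033, ecf: 0.22, composition: {neutral_lipid: 0.0140, phospholipid: 0.0118, water: 0.779}}
  - {name: brain,   flow_frac: 0.0200, volume_frac: 0.0057, ecf: 0.04, composition: {neutral_lipid: 0.0392, phospholipid: 0.0533, water: 0.788}}
  - {name: muscle,  flow_frac: 0.2780, volume_frac: 0.4040, ecf: 0.14, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
  - {name: adipose, flow_frac: 0.0700, volume_frac: 0.0700, ecf: 0.15, composition: {neutral_lipid: 0.8530, phospholipid: 0.0016, water: 0.120}}
  - {name: skin,    flow_frac: 0.0580, volume_frac: 0.1900, ecf: 0.35, composition: {neutral_lipid: 0.0239, phospholipid: 0.0180, water: 0.651}}
  - {name: bone,    flow_frac: 0.0500, volume_frac: 0.0500, ecf: 0.12, composition: {neutral_lipid: 0.0273, phospholipid: 0.0027, water: 0.446}}
  - {name: rest,    flow_frac: 0.1672, volume_frac: 0.1451, ecf: 0.20, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
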