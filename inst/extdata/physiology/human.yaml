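# Human physiology: 13-year-old, 50-kg male (adolescent Ewing sarcoma setting).
# Sources: fractional organ weights/flows from Brown et al. (1997) Toxicol Ind
# Health 13:407 (adult fractions, adolescent-adjusted brain/adipose), cardiac
# output scaled to 50 kg; blood volume 70 mL/kg; absolute GFR fixed at
# 100 mL/min (6 L/h) for a 13-y, 50-kg male (~120 mL/min/1.73 m2 at BSA 1.5 m2).
# Tissue lipid/phospholipid/water volume fractions from Poulin & Theil (2002)
# J Pharm Sci 91:129 (rat tissue composition, reused across species); plasma
# composition uses the human values from the same source.
# Units: body_weight_kg kg; cardiac_output_L_h, gfr_L_h L/h; volumes L (tissue
# density taken as 1 kg/L); flow_frac = fraction of cardiac output (lung carries
# the full cardiac output in series; liver flow_frac is the hepatic artery only,
# portal inflow from gut and spleen is added by the model).
species: human
body_weight_kg: 50
cardiac_output_L_h: 276        # ~4.6 L/min at 50 kg
gfr_L_h: 6.0                   # 100 mL/min, documented constant, overridable
blood_volume_L: 3.5            # 70 mL/kg
plasma_composition: {neutral_lipid: 0.0035, phospholipid: 0.00225, water: 0.945}
tissues:
  - {name: lung,    flow_frac: 1.000, volume_frac: 0.0076, ecf: 0.35, composition: {neutral_lipid: 0.0219, phospholipid: 0.0140, water: 0.811}}
  - {name: liver,   flow_frac: 0.065, volume_frac: 0.0260, ecf: 0.25, composition: {neutral_lipid: 0.0138, phospholipid: 0.0303, water: 0.705}}
  - {name: kidney,  flow_frac: 0.190, volume_frac: 0.0044, ecf: 0.30, composition: {neutral_lipid: 0.0123, phospholipid: 0.0284, water: 0.771}}
  - {name: gut,     flow_frac: 0.150, volume_frac: 0.0170, ecf: 0.30, composition: {neutral_lipid: 0.0292, phospholipid: 0.0138, water: 0.749}}
  - {name: spleen,  flow_frac: 0.020, volume_frac: 0.0026, ecf: 0.30, composition: {neutral_lipid: 0.0077, phospholipid: 0.0136, water: 0.771}}
  - {name: heart,   flow_frac: 0.040, volume_frac: 0.0047, ecf: 0.22, composition: {neutral_lipid: 0.0140, phospholipid: 0.0118, water: 0.779}}
  - {name: brain,   flow_frac: 0.120, volume_frac: 0.0280, ecf: 0.04, composition: {neutral_lipid: 0.0392, phospholipid: 0.0533, water: 0.788}}
  - {name: muscle,  flow_frac: 0.170, volume_frac: 0.4000, ecf: 0.14, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
  - {name: adipose, flow_frac: 0.050, volume_frac: 0.1700, ecf: 0.15, composition: {neutral_lipid: 0.8530, phospholipid: 0.0016, water: 0.120}}
  - {name: skin,    flow_frac: 0.058, volume_frac: 0.0370, ecf: 0.35, composition: {neutral_lipid: 0.0239, phospholipid: 0.0180, water: 0.651}}
  - {name: bone,    flow_frac: 0.050, volume_frac: 0.0800, ecf: 0.12, composition: {neutral_lipid: 0.0273, phospholipid: 0.0027, water: 0.446}}
  - {name: rest,    flow_frac: 0.087, volume_frac: 0.1527, ecf: 0.20, composition: {neutral_lipid: 0.0100, phospholipid: 0.0090, water: 0.756}}
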