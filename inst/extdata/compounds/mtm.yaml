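# Mithramycin (MTM) drug-specific model inputs.
# fup and bpr are fractions/ratios per species; spec_pstc is the specific
# permeability-surface-area product (mL/s per mL tissue cell volume) optimized
# against mouse IV plasma PK and held constant across species.
name: MTM
mw: 1085.2                # g/mol
logp: 1.281
solubility_mg_ml: 0.965
solubility_ph: 5.359
pka: [10.79, 4.89]
fup:
  mouse: 0.0255
  rat: 0.1665
  monkey: 0.1186
  human: 0.1826
bpr:
  mouse: 0.626
  rat: 0.895
  monkey: 0.671           # assumed same as human
  human: 0.671
spec_pstc: 2.95e-2        # mouse-optimized
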