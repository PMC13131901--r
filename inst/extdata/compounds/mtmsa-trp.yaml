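# MTMSA-Trp (tryptophan-conjugated mithramycin analog) drug-specific inputs.
# Mouse and human fup were below the quantification limit (<1%) and are entered
# as 0.001. Monkey BPR 0.02 was adjusted to fit monkey plasma PK.
name: MTMSA-Trp
mw: 1227.3                # g/mol
logp: 2.605
solubility_mg_ml: 0.416
solubility_ph: 5.721
pka: [13.45, 10.81, 6.79]
fup:
  mouse: 0.001            # <1%, assumed 0.1%
  rat: 0.0338
  monkey: 0.0106
  human: 0.001            # <1%, assumed 0.1%
bpr:
  mouse: 0.599
  rat: 0.936
  monkey: 0.02            # adjusted to fit monkey plasma PK
  human: 0.661
spec_pstc: 1.23e-4        # mouse-optimized
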